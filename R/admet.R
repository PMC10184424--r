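#' Lipinski rule-of-five verdict
#'
#' Drug-likeness rule with the classical mix of strict and inclusive bounds:
#' no more than 5 H-bond donors, fewer than 10 H-bond acceptors, molecular
#' weight not greater than 500 Da, logP not greater than 5, and fewer than 10
#' rotatable bonds.
#'
#' @param mw molecular weight in daltons.
#' @param logp octanol-water partition coefficient.
#' @param hbd number of hydrogen-bond donors.
#' @param hba number of hydrogen-bond acceptors.
#' @param rotatable_bonds number of rotatable bonds.
#' @return logical vector; `NA` where any input is missing (a missing value
#'   yields verdict "missing", never a silent `FALSE`).
#' @export
lipinski_pass <- function(mw, logp, hbd, hba, rotatable_bonds) {
  out <- hbd <= 5 & hba < 10 & mw <= 500 & logp <= 5 & rotatable_bonds < 10
  miss <- is.na(mw) | is.na(logp) | is.na(hbd) | is.na(hba) | is.na(rotatable_bonds)
  out[miss] <- NA
  out
}

#' Select active components by ADMET rules
#'
#' Applies three screens to a component table: Lipinski's rule of five, oral
#' bioavailability (`ob_percent >= ob_threshold`), and gastrointestinal
#' absorption (`gi_class == "high"`). Rules whose inputs are missing are
#' treated as not applicable and excluded from the combination rather than
#' failing it (otherwise whole herbs lacking OB annotation would be wiped
#' out). A component with every rule missing is inactive and flagged in
#' `admet_missing`. Experimentally validated components are active regardless
#' of any ADMET value.
#'
#' @param records component table from [read_component_table()].
#' @param ob_threshold oral bioavailability cutoff in percent (default 30).
#' @param combine `"all"` (conjunction of applicable rules, the default) or
#'   `"any"` (disjunction).
#' @return a `data.frame` of per-component verdicts with columns
#'   `component_id`, `lipinski_pass`, `ob_pass`, `gi_pass` (logical, `NA` =
#'   rule not applicable), `validated`, `admet_missing` and the final
#'   `active` flag.
#' @export
select_active_components <- function(records, ob_threshold = 30,
                                     combine = c("all", "any")) {
  combine <- match.arg(combine)
  stopifnot(is.numeric(ob_threshold), length(ob_threshold) == 1)
  lip <- lipinski_pass(records$mw, records$logp, records$hbd, records$hba,
                       records$rotatable_bonds)
  ob <- records$ob_percent >= ob_threshold
  gi <- ifelse(is.na(records$gi_class), NA, records$gi_class == "high")

  rules <- cbind(lipinski = lip, ob = ob, gi = gi)
  combined <- apply(rules, 1L, function(r) {
    v <- r[!is.na(r)]
    if (!length(v)) NA
    else if (combine == "all") all(v)
    else any(v)
  })
  admet_missing <- is.na(combined)
  active <- (!admet_missing & combined) | records$validated

  message(sum(active), " of ", nrow(records), " components active (",
          sum(records$validated & (admet_missing | !combined)),
          " by validated override, ", sum(admet_missing),
          " with no applicable ADMET rule)")

  data.frame(component_id = records$component_id,
             lipinski_pass = lip, ob_pass = ob, gi_pass = gi,
             validated = records$validated,
             admet_missing = admet_missing,
             active = active,
             stringsAsFactors = FALSE)
}
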