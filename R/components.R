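#' Read a table of herbal chemical components
#'
#' Parses a delimited text file of formula chemicals with their ADMET
#' descriptors and herb memberships into a component table. One row per
#' component; the `herbs` field holds one or more herb names separated by
#' `";"`.
#'
#' Required columns: `component_id`, `name`, `herbs`, `mw` (molecular weight,
#' Da), `logp`, `hbd` (H-bond donors), `hba` (H-bond acceptors),
#' `rotatable_bonds`. Optional columns: `ob_percent` (oral bioavailability,
#' 0-100), `gi_class` (`high`/`low`), `validated` (logical; experimentally
#' confirmed high-concentration component). Missing numeric values are kept as
#' `NA`, never coerced to zero.
#'
#' @param path path to a tab- or comma-delimited file with a header row.
#' @param sep field separator; defaults to `","` for `.csv` files and tab
#'   otherwise.
#' @return a `data.frame` with one row per component; `herbs` is a list
#'   column of character vectors.
#' @export
read_component_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("component table not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, sep = sep, header = TRUE, quote = "\"",
                           colClasses = "character", strip.white = TRUE,
                           comment.char = "", na.strings = character(0),
                           check.names = TRUE)
  required <- c("component_id", "name", "herbs", "mw", "logp", "hbd", "hba",
                "rotatable_bonds")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("component table is missing columns: ", paste(missing_cols, collapse = ", "))

  n <- nrow(raw)
  # header is line 1, so data row i sits on file line i + 1
  parse_num <- function(col, what, integer = FALSE) {
    x <- trimws(col)
    x[x %in% c("", "NA", "na", ".")] <- NA
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad))
      stop("cannot parse ", what, " value '", x[bad[1]], "' on line ", bad[1] + 1L)
    if (integer) {
      frac <- which(!is.na(out) & out != round(out))
      if (length(frac))
        stop(what, " must be an integer count; got '", x[frac[1]], "' on line ",
             frac[1] + 1L)
      out <- as.integer(round(out))
    }
    out
  }

  id <- trimws(raw$component_id)
  dup <- unique(id[duplicated(id)])
  if (length(dup))
    stop("duplicate component_id: ", paste(dup, collapse = ", "))

  herbs <- lapply(strsplit(trimws(raw$herbs), ";", fixed = TRUE),
                  function(h) unique(trimws(h[nzchar(trimws(h))])))
  empty <- which(lengths(herbs) == 0)
  if (length(empty))
    stop("component ", id[empty[1]], " has no herb membership (line ",
         empty[1] + 1L, ")")

  mw   <- parse_num(raw$mw, "mw")
  logp <- parse_num(raw$logp, "logp")
  hbd  <- parse_num(raw$hbd, "hbd", integer = TRUE)
  hba  <- parse_num(raw$hba, "hba", integer = TRUE)
  rotb <- parse_num(raw$rotatable_bonds, "rotatable_bonds", integer = TRUE)
  for (cnt in list(list(hbd, "hbd"), list(hba, "hba"), list(rotb, "rotatable_bonds"))) {
    neg <- which(!is.na(cnt[[1]]) & cnt[[1]] < 0)
    if (length(neg))
      stop(cnt[[2]], " must be non-negative (line ", neg[1] + 1L, ")")
  }

  ob <- if ("ob_percent" %in% names(raw)) parse_num(raw$ob_percent, "ob_percent")
        else rep(NA_real_, n)
  out_of_range <- which(!is.na(ob) & (ob < 0 | ob > 100))
  if (length(out_of_range))
    stop("ob_percent must lie in [0, 100] (line ", out_of_range[1] + 1L, ")")

  gi <- if ("gi_class" %in% names(raw)) tolower(trimws(raw$gi_class))
        else rep(NA_character_, n)
  gi[gi %in% c("", "na", "missing")] <- NA
  bad_gi <- which(!is.na(gi) & !gi %in% c("high", "low"))
  if (length(bad_gi))
    stop("gi_class must be 'high' or 'low' (line ", bad_gi[1] + 1L, ")")

  validated <- if ("validated" %in% names(raw)) {
    v <- tolower(trimws(raw$validated))
    v %in% c("true", "t", "1", "yes")
  } else rep(FALSE, n)

  out <- data.frame(component_id = id, name = trimws(raw$name),
                    mw = mw, logp = logp, hbd = hbd, hba = hba,
                    rotatable_bonds = rotb, ob_percent = ob, gi_class = gi,
                    validated = validated, stringsAsFactors = FALSE)
  out$herbs <- herbs
  rownames(out) <- NULL
  out
}

#' Write a component table
#'
#' Inverse of [read_component_table()]: serializes the table (list-column
#' `herbs` joined with `";"`) as tab-delimited text.
#'
#' @param components component table as returned by [read_component_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_component_table <- function(components, path) {
  out <- components
  out$herbs <- vapply(components$herbs, paste, character(1), collapse = ";")
  out <- out[, c("component_id", "name", "herbs", "mw", "logp", "hbd", "hba",
                 "rotatable_bonds", "ob_percent", "gi_class", "validated")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
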