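`%||%` <- function(x, y) if (is.null(x)) y else x

# Gene symbols are upper-cased exactly once, at ingest. No alias resolution.
.norm_symbol <- function(x) toupper(trimws(as.character(x)))

.fmt_num <- function(x) {
  # 17 significant digits: doubles survive a write/read round trip bit-for-bit
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else sprintf("%.17g", v)
  }, character(1))
  out
}
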