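# JSON serialization of complex records (text format, round-trips exactly
# at full double precision).

#' Save / load complex records as JSON
#'
#' @param records list of `complex_record`.
#' @param path output `.json` path.
#' @return `path` invisibly (save); list of `complex_record` (load).
#' @export
save_complex_records <- function(records, path) {
  ser_rs <- function(rs) list(chain_id = rs$chain_id, res_seq = rs$res_seq,
                              aa = rs$aa, ss = rs$ss,
                              coords = rs$coords)
  out <- lapply(records, function(cr)
    list(peptide = ser_rs(cr$peptide), site = ser_rs(cr$site),
         oligomeric_label = cr$oligomeric_label,
         provenance = cr$provenance))
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname save_complex_records
#' @export
load_complex_records <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  de_rs <- function(x) {
    n <- length(x$res_seq)
    co <- array(as.numeric(x$coords), dim = c(n, 4, 3))
    ss <- as.character(x$ss)
    ss[ss == "NA" | is.na(ss)] <- NA_character_
    residue_set(x$chain_id, x$res_seq, x$aa, co, ss)
  }
  lapply(raw, function(x)
    complex_record(de_rs(x$peptide), de_rs(x$site),
                   x$oligomeric_label, as.list(x$provenance)))
}
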