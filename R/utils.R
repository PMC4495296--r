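#' @importFrom utils head tail
#' @importFrom stats runif setNames
#' @importFrom data.table data.table setkey setorder := .N fread fwrite
NULL

# one-letter amino-acid alphabet accepted throughout (20 standard + X)
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V", "X")

`%||%` <- function(a, b) if (is.null(a)) b else a

sv_stop <- function(...) stop(sprintf(...), call. = FALSE)

sv_log <- function(verbose, ...) {
  if (isTRUE(verbose)) message(sprintf(...))
}

assert_aa <- function(x, what = "sequence") {
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% AA_ALPHABET)
  if (length(bad) > 0L)
    sv_stop("illegal character '%s' at position %d of %s", chars[bad[1L]],
            bad[1L], what)
  invisible(TRUE)
}

# residue identity used everywhere: author number plus insertion code
res_id <- function(resno, icode = "") {
  icode <- ifelse(is.na(icode) | icode == " ", "", icode)
  paste0(resno, icode)
}

res_key <- function(chain, resno, icode = "") {
  paste0(chain, ":", res_id(resno, icode))
}

# read a TSV with a header into a data.frame, keeping columns as character
# unless asked otherwise
read_tsv <- function(path, colClasses = NULL) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = colClasses, data.table = FALSE,
                          na.strings = NULL)
  dt
}

write_tsv <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, na = "")
  invisible(path)
}
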