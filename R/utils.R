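#' @importFrom stats median rpois sd wilcox.test t.test approx quantile
#' @importFrom utils head tail packageVersion
NULL

# TSV convention used throughout: the header row is prefixed with '#' so that
# downstream tools treating '#' as comment still see a plain TSV body.

write_tsv_hash <- function(df, path, meta = NULL) {
  con <- file(path, open = "wb")  # binary mode: byte-identical across runs/platforms
  on.exit(close(con))
  if (!is.null(meta)) {
    for (m in meta) writeLines(paste0("## ", m), con, sep = "\n")
  }
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con, sep = "\n")
  if (nrow(df)) {
    body <- do.call(paste, c(lapply(df, format_field), list(sep = "\t")))
    writeLines(body, con, sep = "\n")
  }
  invisible(path)
}

format_field <- function(x) {
  if (is.double(x)) {
    out <- formatC(x, digits = 15, format = "g")
    out[is.na(x)] <- "NA"
    out
  } else {
    as.character(x)
  }
}

read_tsv_hash <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "## ")]
  if (!length(lines)) stop("empty TSV: ", path)
  header <- sub("^#", "", lines[[1]])
  txt <- paste(c(header, lines[-1]), collapse = "\n")
  data.table::fread(text = txt, sep = "\t", header = TRUE, data.table = FALSE)
}

# Stable 31-adic string hash mod a large prime; used to derive per-gene RNG
# substreams so that adding/removing genes never perturbs other genes' draws.
stable_hash <- function(s) {
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * 31 + c) %% 1000000007
  h
}

derive_seed <- function(master_seed, key) {
  as.integer((as.numeric(master_seed) * 48271 + stable_hash(key)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
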