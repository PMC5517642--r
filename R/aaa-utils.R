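# Internal string/sequence helpers. Sequences are stored as given (RNA oligos
# with U, genomes with T); comparisons canonicalize U->T.

DNA_BASES <- c("A", "C", "G", "T")
RNA_BASES <- c("A", "C", "G", "U")

u2t <- function(x) chartr("Uu", "Tt", toupper(x))

t2u <- function(x) chartr("Tt", "Uu", toupper(x))

#' Reverse complement of DNA/RNA strings
#'
#' U is canonicalized to T before complementing; output is DNA alphabet.
#'
#' @param x character vector of sequences over \{A,C,G,T,U,N\}.
#' @return character vector of reverse complements (DNA alphabet).
#' @export
revcomp <- function(x) {
  x <- u2t(x)
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, ""), function(ch) paste(rev(ch), collapse = ""), "")
}

# split a string into a character vector of single bases
str_bases <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

# all k-mers over an alphabet, in lexicographic order of the alphabet given
all_kmers <- function(k, alphabet = DNA_BASES) {
  grid <- do.call(expand.grid,
                  c(rep(list(alphabet), k),
                    list(KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)))
  # expand.grid varies the first factor fastest; reverse for left-to-right order
  do.call(paste0, rev(grid))
}

hamming <- function(a, b) {
  sum(str_bases(a) != str_bases(b))
}

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

warn_fmt <- function(...) warning(sprintf(...), call. = FALSE)

#' Write a data frame as TSV
#'
#' Tab-separated, header row, UTF-8, `.` for missing values.
#'
#' @param x data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a TSV written by this package
#'
#' @param path input path.
#' @return data frame with `.` read back as NA.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    na.strings = ".", stringsAsFactors = FALSE,
                    comment.char = "", fileEncoding = "UTF-8")
}

# derive a stream of child seeds from one integer seed, staying < 2^31
derive_seed <- function(seed, i) {
  (as.integer(seed) + 1013L * as.integer(i)) %% 2147483587L
}
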