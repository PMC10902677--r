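# Fixture builders and independent oracles shared across the test files.
# All fixtures are constructed in code; files are written to tempdirs.

# a repertoire from amino-acid sequences; nucleotide sequences are
# synthesized as 3x-length placeholders unless supplied
make_rep <- function(aa, counts = rep(1, length(aa)), sample = "s",
                     nt = NULL, ids = NULL) {
  nt <- nt %||% vapply(aa, function(s) strrep("GCT", nchar(s)), character(1))
  ids <- ids %||% sprintf("c%03d", seq_along(aa))
  repertoire(clone_id = ids, read_count = counts, nt_seq = nt, aa_seq = aa,
             sample_name = sample)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

write_mixcr_fixture <- function(path, readCount, readFraction = NULL,
                                nSeqCDR3, aaSeqCDR3,
                                cloneId = seq_along(readCount),
                                extra = NULL, drop_cols = character()) {
  readFraction <- readFraction %||% (readCount / sum(readCount))
  tab <- data.frame(cloneId = cloneId, readCount = readCount,
                    readFraction = readFraction, nSeqCDR3 = nSeqCDR3,
                    aaSeqCDR3 = aaSeqCDR3, stringsAsFactors = FALSE)
  if (!is.null(extra)) tab <- cbind(tab, extra)
  tab <- tab[, setdiff(names(tab), drop_cols), drop = FALSE]
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  path
}

write_airr_fixture <- function(path, junction, junction_aa,
                               duplicate_count = NULL,
                               sequence_id = seq_along(junction),
                               drop_cols = character()) {
  tab <- data.frame(sequence_id = sequence_id, junction = junction,
                    junction_aa = junction_aa, stringsAsFactors = FALSE)
  if (!is.null(duplicate_count)) tab$duplicate_count <- duplicate_count
  tab <- tab[, setdiff(names(tab), drop_cols), drop = FALSE]
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  path
}

random_aa <- function(n, len_range = c(6, 14)) {
  vapply(seq_len(n), function(i) {
    L <- sample(seq(len_range[1], len_range[2]), 1)
    paste(sample(aa_alphabet(), L, replace = TRUE), collapse = "")
  }, character(1))
}

# --- independent direct-enumeration oracles for the overlap indices ----

oracle_set_counts <- function(A, B) {
  A <- unique(A); B <- unique(B)
  inter <- 0
  for (a in A) for (b in B) if (identical(a, b)) inter <- inter + 1
  un <- length(A)
  for (b in B) if (!any(vapply(A, identical, logical(1), b))) un <- un + 1
  list(inter = inter, union = un, na = length(A), nb = length(B))
}

oracle_jaccard <- function(A, B) {
  s <- oracle_set_counts(A, B)
  s$inter / s$union
}

oracle_dice <- function(A, B) {
  s <- oracle_set_counts(A, B)
  2 * s$inter / (s$na + s$nb)
}

oracle_relative <- function(A, B) {
  s <- oracle_set_counts(A, B)
  s$inter / min(s$na, s$nb)
}

# Morisita-Horn by explicit looping over the union of sequences
oracle_morisita_horn <- function(xa, xb) {
  seqs <- unique(c(names(xa), names(xb)))
  num <- 0; sx2 <- 0; sy2 <- 0; X <- 0; Y <- 0
  for (s in seqs) {
    x <- if (s %in% names(xa)) xa[[s]] else 0
    y <- if (s %in% names(xb)) xb[[s]] else 0
    num <- num + x * y
    sx2 <- sx2 + x^2
    sy2 <- sy2 + y^2
    X <- X + x
    Y <- Y + y
  }
  2 * num / ((sx2 / X^2 + sy2 / Y^2) * X * Y)
}

# plain-R recursive Levenshtein oracle for small strings
ld_rec_r <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  if (na == 0) return(nb)
  if (nb == 0) return(na)
  cost <- if (substr(a, na, na) == substr(b, nb, nb)) 0 else 1
  min(ld_rec_r(substr(a, 1, na - 1), b) + 1,
      ld_rec_r(a, substr(b, 1, nb - 1)) + 1,
      ld_rec_r(substr(a, 1, na - 1), substr(b, 1, nb - 1)) + cost)
}

# all strings over `alphabet` with lengths 0..max_len
all_strings_upto <- function(alphabet, max_len) {
  out <- ""
  cur <- ""
  for (L in seq_len(max_len)) {
    cur <- as.vector(outer(cur, alphabet, paste0))
    out <- c(out, cur)
  }
  out
}
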