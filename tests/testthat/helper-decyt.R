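# Shared builders and independent oracles for the test suite.

panel7 <- function() default_panel()

# Small deterministic event table on the transformed scale.
make_table <- function(n = 50, sample_id = "s1", seed = 1, markers = panel7(),
                       transformed = TRUE, shift = 0) {
  m <- with(list(), {
    set.seed(seed)
    matrix(rnorm(n * length(markers), mean = 1 + shift, sd = 0.3), nrow = n,
           dimnames = list(NULL, unclass(markers)))
  })
  event_table(m, sample_id = sample_id, transformed = transformed)
}

# 5 vs 4 sample set of Gaussian noise (transformed scale).
make_sample_set <- function(n = 60, seed = 1) {
  ids <- c(paste0("y", 1:5), paste0("o", 1:4))
  tables <- lapply(seq_along(ids), function(i)
    make_table(n, sample_id = ids[i], seed = seed + i))
  meta <- data.frame(sample_id = ids,
                     condition = rep(c("young", "aged"), c(5, 4)))
  assemble_sample_set(tables, meta, reference = "young")
}

# FCS writer independent of the package's, with distinct detector ($PnN) and
# stain ($PnS) names; used to probe marker resolution and as a second opinion
# on the binary layout.
write_fcs_custom <- function(mat, pnn, pns, path) {
  n <- nrow(mat); p <- ncol(mat)
  delim <- "\\"
  kw <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
          "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
          "$BEGINDATA", "%BD%", "$ENDDATA", "%ED%",
          "$BYTEORD", "1,2,3,4", "$DATATYPE", "F", "$MODE", "L",
          "$NEXTDATA", "0", "$PAR", as.character(p), "$TOT", as.character(n))
  for (j in seq_len(p)) {
    kw <- c(kw, sprintf("$P%dB", j), "32", sprintf("$P%dE", j), "0,0",
            sprintf("$P%dR", j), "262144",
            sprintf("$P%dN", j), pnn[j])
    if (!is.na(pns[j])) kw <- c(kw, sprintf("$P%dS", j), pns[j])
  }
  text_of <- function(kw) paste0(delim, paste0(kw, collapse = delim), delim)
  kw[kw == "%BD%"] <- "0000000000"; kw[kw == "%ED%"] <- "0000000000"
  text <- text_of(kw)
  ts <- 58L; te <- ts + nchar(text) - 1L
  ds <- ts + nchar(text); de <- ds + 4L * n * p - 1L
  kw[which(kw == "$BEGINDATA") + 1L] <- sprintf("%010d", ds)
  kw[which(kw == "$ENDDATA") + 1L] <- sprintf("%010d", de)
  text <- text_of(kw)
  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d", ts, te, ds, de, 0L, 0L)
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(text), con)
  writeBin(as.numeric(t(mat)), con, size = 4L, endian = "little")
  path
}

# Brute-force oracles -------------------------------------------------------

oracle_median <- function(v) {
  s <- sort(v); n <- length(s)
  if (n %% 2L == 1L) s[(n + 1L) / 2L] else (s[n / 2L] + s[n / 2L + 1L]) / 2
}

# Median-of-ratios size factors, coded independently from the formula with
# explicit loops.
oracle_size_factors <- function(counts) {
  m <- nrow(counts); k <- ncol(counts)
  usable <- logical(m)
  for (c in seq_len(m)) usable[c] <- all(counts[c, ] > 0)
  geo <- numeric(m)
  for (c in seq_len(m)) geo[c] <- exp(sum(log(counts[c, ])) / k)
  s <- numeric(k)
  for (j in seq_len(k)) {
    ratios <- numeric(0)
    for (c in seq_len(m)) {
      if (usable[c]) ratios <- c(ratios, counts[c, j] / geo[c])
    }
    s[j] <- oracle_median(ratios)
  }
  s
}

oracle_tally <- function(labels_df, ids, n_clusters) {
  out <- matrix(0L, n_clusters, length(ids),
                dimnames = list(paste0("c", seq_len(n_clusters)), ids))
  for (r in seq_len(nrow(labels_df))) {
    out[labels_df$cluster[r], labels_df$sample_id[r]] <-
      out[labels_df$cluster[r], labels_df$sample_id[r]] + 1L
  }
  out
}

# Partition agreement ignoring label identities (adjusted Rand index).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
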