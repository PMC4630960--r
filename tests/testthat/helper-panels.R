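# Shared fixtures and independent oracles used across the suite.

# Naive pyrogram oracle: advances one template base at a time, independent of
# the run-length implementation under test.
naive_pyrogram <- function(sequence, dispensations) {
  s <- strsplit(sequence, "")[[1]]
  d <- strsplit(dispensations, "")[[1]]
  h <- numeric(length(d))
  pos <- 1L
  for (j in seq_along(d)) {
    while (pos <= length(s) && s[pos] == d[j]) {
      h[j] <- h[j] + 1
      pos <- pos + 1L
    }
  }
  h
}

# Table-lookup reverse complement oracle.
naive_revcomp <- function(sequence) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(sequence, "")[[1]]]), collapse = "")
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Minimal single-SNP panel.
toy_panel <- function(uns_ref = "AC", uns_alt = "AG", order = NULL,
                      ploidy = 2) {
  diffs <- which(strsplit(uns_ref, "")[[1]] != strsplit(uns_alt, "")[[1]])
  if (length(diffs) != 1) diffs <- 1 # let snp_panel() raise its own error
  snp_panel(
    tibble::tibble(
      snp_id = "toy1",
      allele_ref = substr(uns_ref, diffs, diffs),
      allele_alt = substr(uns_alt, diffs, diffs),
      uns_ref = uns_ref, uns_alt = uns_alt,
      orientation = "forward", as_read = TRUE, ploidy = ploidy,
      maf = 0.3, allelic_or = 1.1
    ),
    dispensation_order = order, name = "toy"
  )
}

# Two-SNP panel used by the order-design tests.
toy_panel2 <- function(order = NULL) {
  snp_panel(
    tibble::tibble(
      snp_id = c("toyA", "toyB"),
      allele_ref = c("C", "T"),
      allele_alt = c("G", "A"),
      uns_ref = c("AC", "GT"),
      uns_alt = c("AG", "GA"),
      orientation = "forward", as_read = TRUE, ploidy = 2,
      maf = 0.25, allelic_or = 1.0
    ),
    dispensation_order = order, name = "toy2"
  )
}

# All dispensation orders up to max_len without consecutive repeats.
all_orders <- function(max_len) {
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  frontier <- bases
  for (len in seq_len(max_len)) {
    out <- c(out, frontier)
    if (len < max_len) {
      frontier <- unlist(lapply(frontier, function(o) {
        last <- substr(o, nchar(o), nchar(o))
        paste0(o, setdiff(bases, last))
      }))
    }
  }
  out
}
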