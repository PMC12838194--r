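# Small fixtures shared across test files; everything is built in code.

tiny_otu_table <- function() {
  m <- matrix(c(5L, 2L, 1L,
                0L, 3L, 4L,
                3L, 1L, 0L,
                2L, 4L, 6L), nrow = 3,
              dimnames = list(c("s1", "s2", "s3"),
                              c("OTU_1", "OTU_2", "OTU_3", "OTU_4")))
  otu_table(m,
            group = c("cultivated", "cultivated", "control"),
            domain = rep("prokaryote", 3),
            taxonomy = paste0("k__Microbes;p__Phy", c(1, 1, 2, 2)))
}

balanced_cherry_tree <- function() {
  ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
}

two_clade_table <- function() {
  m <- matrix(c(1L, 0L,
                1L, 0L,
                0L, 1L,
                0L, 1L), nrow = 2,
              dimnames = list(c("s1", "s2"), c("A", "B", "C", "D")))
  otu_table(m, group = c("cultivated", "control"),
            domain = rep("prokaryote", 2))
}

# Plain double-loop betaMNTD, independent of the compiled kernel.
bmntd_bruteforce <- function(counts, D) {
  rel <- sweep(counts, 1, rowSums(counts), "/")
  n <- nrow(counts)
  out <- matrix(0, n, n, dimnames = list(rownames(counts), rownames(counts)))
  for (k in seq_len(n)) {
    for (l in seq_len(n)) {
      if (k == l) next
      pk <- which(counts[k, ] > 0)
      pl <- which(counts[l, ] > 0)
      t1 <- sum(vapply(pk, function(i) {
        rel[k, i] * min(D[colnames(counts)[i], colnames(counts)[pl]])
      }, numeric(1)))
      t2 <- sum(vapply(pl, function(j) {
        rel[l, j] * min(D[colnames(counts)[j], colnames(counts)[pk]])
      }, numeric(1)))
      out[k, l] <- 0.5 * (t1 + t2)
    }
  }
  out
}

small_chip <- function(ct_sd = 0, fold = c(1, 0.5, 0.25), seed = 1) {
  simulate_genechip(genes = c("gA", "gB", "gC"),
                    cycle_labels = c("C", "N", "P"),
                    control_ct_means = c(22, 23, 24),
                    fold = fold, replicates = 5, ct_sd = ct_sd, seed = seed)
}
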