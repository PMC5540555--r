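# Shared fixtures and independent oracles, all built in code.

BASES <- c("A", "C", "G", "T")

random_30mers <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n),
         function(i) paste0(sample(BASES, 30L, replace = TRUE),
                            collapse = ""),
         character(1L))
}

# Independent naive featurization oracle: walk the sequence with substr()
# and fill a named vector by feature-name lookup. Shares no code with the
# package's arithmetic k-mer encoding.
naive_position_specific <- function(seq, k) {
  kmers <- sort(do.call(paste0, expand.grid(rep(list(BASES), k))[
    , k:1, drop = FALSE]))
  nm <- as.vector(t(outer(seq_len(31L - k), kmers,
                          function(p, w) paste0(w, "_", p))))
  v <- stats::setNames(numeric(length(nm)), nm)
  hits <- vapply(seq_len(31L - k),
                 function(p) paste0(substr(seq, p, p + k - 1L), "_", p),
                 character(1L))
  v[match(hits, nm)] <- 1
  v
}

naive_position_independent <- function(seq, k) {
  kmers <- sort(do.call(paste0, expand.grid(rep(list(BASES), k))[
    , k:1, drop = FALSE]))
  v <- stats::setNames(numeric(length(kmers)), kmers)
  for (p in seq_len(31L - k)) {
    w <- substr(seq, p, p + k - 1L)
    v[w] <- v[w] + 1
  }
  v
}

# Brute-force MCC oracle: explicit confusion matrix at one threshold.
brute_mcc <- function(predictions, labels, threshold) {
  pos <- predictions >= threshold
  tp <- sum(pos & labels == 1); fp <- sum(pos & labels == 0)
  fn <- sum(!pos & labels == 1); tn <- sum(!pos & labels == 0)
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / denom
}

# Small labeled dataset for model/evaluation tests.
toy_dataset <- function(n = 60L, n_genes = 3L, seed = 42L,
                        noise_sd = 0.5) {
  sim <- simulate_guides(simulation_config(
    n_guides = n, n_genes = n_genes, noise_sd = noise_sd, seed = seed
  ))
  sim
}

# Reduced feature specification for structural tests where the full
# 9632-column encoding is not the point.
small_spec <- function() {
  feature_spec(kmax_position_specific = 2L, kmax_position_independent = 2L,
               include_thermodynamic = FALSE, include_auxiliary = FALSE)
}

write_toy_csv <- function(path, sequences, genes, scores,
                          extra_cols = list()) {
  df <- data.frame(
    `30mer` = sequences, `Target gene` = genes,
    score_drug_gene_rank = scores,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  for (nm in names(extra_cols)) df[[nm]] <- extra_cols[[nm]]
  utils::write.csv(df, path, row.names = FALSE)
  path
}
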