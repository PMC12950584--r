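# In-code fixtures shared across test files.

# abundance table over the full SBP-MI + HBCDI genus set from a named list
# of per-sample abundances; unnamed genera are 0.
index_genera <- function() {
  c("Streptococcus", "Escherichia-Shigella", "Klebsiella", "Veillonella",
    "Prevotella", "Roseburia", "Faecalibacterium", "Bacteroides",
    "Lactobacillus", "Ruminococcus")
}

make_table <- function(samples) {
  genera <- index_genera()
  m <- matrix(0, nrow = length(samples), ncol = length(genera),
              dimnames = list(names(samples), genera))
  for (s in names(samples)) {
    m[s, names(samples[[s]])] <- samples[[s]]
  }
  abundance_table(m)
}

# random positive composition over the index genera
rand_table <- function(n, seed) {
  set.seed(seed)
  genera <- index_genera()
  m <- matrix(stats::rgamma(n * length(genera), shape = 0.8), nrow = n,
              dimnames = list(sprintf("s%03d", seq_len(n)), genera))
  abundance_table(m / rowSums(m))
}

# closed-form Firth estimate for a single binary covariate: equivalent to
# adding 1/2 to each cell of the 2x2 table (a, b = events/non-events at
# x = 1; c, d = events/non-events at x = 0)
firth_2x2_closed_form <- function(a, b, c, d) {
  c(intercept = log((c + 0.5) / (d + 0.5)),
    slope = log(((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))))
}

# one-group cohort config over the default panel (NSBP-like composition)
single_group_config <- function(n, inr = c(1.5, 0.3), meld = c(12, 3),
                                history = 0.1, seed = 1) {
  dp <- sbpmi:::default_dirichlet_params()
  dp <- rbind(dp, G = dp["NSBP", ])
  cohort_config(group_sizes = c(G = n), dirichlet_params = dp,
                clinical_model = list(G = list(inr = inr, meld = meld,
                                               history = history)),
                paired_group = "G", seed = seed)
}

# per-subject index deltas of a paired follow-up cohort
paired_deltas <- function(pf, definition) {
  md <- pf$metadata
  vals <- unclass(pf$abundance)
  bi <- compute_index(abundance_table(vals[md$timepoint == "baseline", ,
                                           drop = FALSE]), definition)
  fi <- compute_index(abundance_table(vals[md$timepoint == "followup", ,
                                           drop = FALSE]), definition)
  compute_delta(bi, fi, md)
}

firth_2x2_data <- function(a, b, c, d) {
  data.frame(x = rep(c(1, 0), times = c(a + b, c + d)),
             y = c(rep(1, a), rep(0, b), rep(1, c), rep(0, d)))
}
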