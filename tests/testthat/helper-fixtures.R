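# Shared fixtures: all test data are generated in code.

# small generic cohort used across module tests
tiny_sim <- function(n = c(8, 8, 8), effect = 1, seed = 3, n_roi = 5, n_snp = 4,
                     inform = c(imaging = 2, genetics = 2, clinical = 2),
                     noise = 1.5) {
  simulate_cohort(cohort_spec(n_per_class = n, n_roi = n_roi, n_snp = n_snp,
                              n_informative = inform, effect_size = effect,
                              traj_noise_sd = noise),
                  seed = seed)
}

# reduced architecture used wherever a transformer must actually train in a
# test: k = 8..64, 2 layers; the optimization settings (lr 1e-3, small
# epoch budgets) are part of the declared reduced configuration
tiny_config <- function(k = 8, heads = 2, hidden = 6, epochs = 2, lr = 1e-3,
                        dropout = 0, batch = 8, seed = 5, ...) {
  tricoat_config(k = k, n_layers = 2, n_heads = heads, mlp_hidden = hidden,
                 epochs = epochs, lr = lr, dropout = dropout,
                 batch_size = batch, seed = seed, ...)
}

scaled_inputs <- function(sim) {
  scaled <- apply_scaler(sim$cohort, fit_scaler(sim$cohort, sim$cohort$subjects))
  tricoat:::model_inputs(scaled)
}

strat_split <- function(truth, frac = 0.75, seed = 1) {
  set.seed(seed)
  tr <- unlist(lapply(split(as.character(truth$subject_id), truth$subtype),
                      function(ids) sample(ids, round(frac * length(ids)))))
  list(train = sort(unname(tr)),
       test = sort(setdiff(truth$subject_id, tr)))
}

truth_of <- function(sim, ids) {
  as.character(sim$truth$subtype[match(ids, sim$truth$subject_id)])
}

prob_matrix <- function(prob_tbl) {
  P <- as.matrix(prob_tbl[, c("slow", "intermediate", "fast")])
  rownames(P) <- prob_tbl$subject_id
  P
}
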