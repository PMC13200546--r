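#' Full clusterability-classification study protocol
#'
#' Runs the complete synthetic sweep (p_intra, p_inter over 0.1..1.0 in
#' steps of 0.1, `replicates` graphs per cell, 200-node equal-block SBMs),
#' labels each graph by spectral recovery of the planted partition
#' binarized at `tau`, splits 75/25, trains the requested classifiers, and
#' reports their held-out metrics — once per sweep seed, then averaged.
#'
#' @param seeds Integer vector of sweep seeds (each seed generates an
#'   independent sweep and split).
#' @param model_kinds Classifier kinds to fit (see [train_cdi()]).
#' @param replicates,n_nodes,tau Sweep parameters (defaults: 10 replicates
#'   per cell, 200 nodes, tau 0.7).
#' @return Data frame of averaged test metrics, one row per model kind.
#' @export
cdi_sweep_protocol <- function(seeds = 1:3,
                               model_kinds = c("logistic", "svm",
                                               "random_forest", "knn"),
                               replicates = 10, n_nodes = 200, tau = 0.7) {
  per_seed <- lapply(seeds, function(s) {
    ts <- build_training_set(replicates = replicates, n_nodes = n_nodes,
                             tau = tau, seed = s)
    m <- train_cdi(ts, model_kinds = model_kinds,
                   split_seed = derive_seed(s, "protocol-split"))
    m$metrics
  })
  out <- per_seed[[1]]
  cols <- c("accuracy", "precision", "recall", "f1")
  for (cn in cols) {
    out[[cn]] <- rowMeans(vapply(per_seed, function(m) m[[cn]],
                                 numeric(nrow(out))))
  }
  out
}
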