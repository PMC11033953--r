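#' Model configuration
#'
#' Defaults follow the published sensitivity analysis where stated: two
#' propagation layers and four subgraphs. The embedding dimension, MLP hidden
#' width, LeakyReLU slope and assignment temperature are not stated there;
#' their defaults follow common LightGCN practice and are documented in the
#' methods vignette.
#'
#' @param L embedding dimension (default 64).
#' @param K total propagation depth (>= 1; default 2). The first-order
#'   aggregation is layer 1; subgraph-restricted aggregations are layers 2..K.
#' @param n_subgraphs number of subgraphs N_s (default 4).
#' @param leaky_slope negative slope of LeakyReLU (default 0.01).
#' @param mlp_hidden hidden width of the assignment MLP (default `L`).
#' @param ablation_lightgcn if `TRUE`, skip subgraph generation entirely and
#'   run K plain LightGCN layers on the full graph.
#' @param assignment_mode `"straight_through"` (hard forward, soft gradient),
#'   `"hard"` (generator effectively frozen), or `"soft"` (fully relaxed
#'   membership weights; used as a differentiability oracle).
#' @param temperature softmax temperature for the relaxed assignment.
#' @param balance_weight weight of the usage-balance term
#'   `KL(mean soft assignment || uniform)` added to the training loss in the
#'   relaxed assignment modes. Without it the partition provably collapses
#'   into a single subgraph early in training (aggregate winner-take-all
#'   feedback through the softmax); the term penalizes only the aggregate
#'   usage, not per-snoRNA confidence. Set 0 to disable.
#' @param seed seed for parameter initialization.
#' @return An object of class `model_config`.
#' @export
model_config <- function(L = 64L, K = 2L, n_subgraphs = 4L,
                         leaky_slope = 0.01, mlp_hidden = NULL,
                         ablation_lightgcn = FALSE,
                         assignment_mode = c("straight_through", "hard", "soft"),
                         temperature = 1.0, balance_weight = 1.0, seed = 1L) {
  assignment_mode <- match.arg(assignment_mode)
  L <- as.integer(L); K <- as.integer(K); n_subgraphs <- as.integer(n_subgraphs)
  if (L < 1) stop("L must be >= 1")
  if (K < 1) stop("K must be >= 1")
  if (n_subgraphs < 1) stop("n_subgraphs must be >= 1")
  if (temperature <= 0) stop("temperature must be positive")
  if (balance_weight < 0) stop("balance_weight must be non-negative")
  structure(
    list(L = L, K = K, n_subgraphs = n_subgraphs,
         leaky_slope = leaky_slope,
         mlp_hidden = as.integer(mlp_hidden %||% L),
         ablation_lightgcn = isTRUE(ablation_lightgcn),
         assignment_mode = assignment_mode,
         temperature = temperature, balance_weight = balance_weight,
         seed = as.integer(seed)),
    class = "model_config"
  )
}

#' Training configuration
#'
#' Learning rate and L2 strength follow the published sensitivity analysis
#' (lr = 0.001, lambda = 0.1). Optimizer (Adam), epoch budget, batch size and
#' negative-sampling rate are not stated there; defaults are conventional for
#' BPR-trained graph recommenders.
#'
#' @param lr Adam learning rate.
#' @param lambda L2 regularization strength on ego embeddings and generator
#'   weights.
#' @param epochs number of training epochs.
#' @param batch_size triplets per optimizer step; `NULL` (default) trains
#'   full-batch for determinism.
#' @param neg_per_pos negative diseases sampled per observed association.
#' @param patience early-stopping patience in epochs on validation AUC
#'   (active only when validation pairs are supplied).
#' @param eval_every validation-AUC evaluation cadence in epochs.
#' @param seed seed governing triplet sampling and initialization order.
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr = 0.001, lambda = 0.1, epochs = 1000L,
                         batch_size = NULL, neg_per_pos = 1L,
                         patience = 50L, eval_every = 10L, seed = 1L) {
  if (lr <= 0) stop("lr must be positive")
  if (lambda < 0) stop("lambda must be non-negative")
  epochs <- as.integer(epochs)
  if (epochs < 0) stop("epochs must be >= 0")
  structure(
    list(lr = lr, lambda = lambda, epochs = epochs,
         batch_size = if (is.null(batch_size)) NULL else as.integer(batch_size),
         neg_per_pos = as.integer(neg_per_pos),
         patience = as.integer(patience),
         eval_every = as.integer(eval_every),
         seed = as.integer(seed)),
    class = "train_config"
  )
}
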