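#' Fit a neural destination-choice model
#'
#' Trains a feed-forward neural scorer that predicts, for each
#' origin-destination pair, the share of the origin's out-migrants choosing
#' that destination, as a nonlinear function of the four spatial-interaction
#' features: origin population, destination population, great-circle
#' distance and intervening opportunities. This is the trainable counterpart
#' to the fixed-form radiation family — same features, free functional form.
#'
#' Training data are an observed flow table joined to a feature table over
#' (`origin_id`, `dest_id`); pairs present in `features` but absent from
#' `flows` are zero flows. Each origin's flows are converted to shares of
#' its total outflow, and a single-hidden-layer network (logistic output) is
#' fit to the shares by cross-entropy, with inputs
#' `log m_i, log m_j, log d_km, log(1 + s_ij)` standardised internally.
#' Origins with zero outflow are dropped. At prediction time raw scores are
#' renormalised within each origin, so predicted rows are probability
#' distributions over the offered destination set regardless of the output
#' scale.
#'
#' Training is deterministic given `seed` (initial weights and the
#' train/validation origin split both derive from it); refitting with the
#' same data and seed reproduces the weights bitwise. When `holdout > 0`
#' that fraction of origins is held out and the fit with the best held-out
#' cross-entropy across `restarts` random restarts is kept.
#'
#' @param flows flow table with `origin_id`, `dest_id`, `migrants` columns.
#' @param features feature table from [build_feature_table()] covering every
#'   origin in `flows` and its allowed destinations.
#' @param hidden hidden-layer size (default 24 units).
#' @param decay L2 weight decay passed to [nnet::nnet()].
#' @param maxit maximum optimiser iterations.
#' @param holdout fraction of origins held out for restart selection.
#' @param restarts number of random restarts.
#' @param seed integer seed controlling initial weights and the origin split.
#' @return an object of class `c("migration_ann", "migration_model")` with a
#'   [predict()] method taking a feature table.
#' @export
fit_migration_ann <- function(flows, features, hidden = 24, decay = 1e-4,
                              maxit = 600, holdout = 0.2, restarts = 2,
                              seed = 1) {
  check_columns(flows, c("origin_id", "dest_id", "migrants"), "flow table")
  check_columns(features, c("origin_id", "dest_id", "m_i", "m_j", "d_km",
                            "s_ij"), "feature table")
  if (all(flows$migrants == 0)) {
    stop_slrmig("degenerate training set: all flows are zero")
  }
  train_origins <- unique(flows$origin_id)
  feats <- features[features$origin_id %in% train_origins, , drop = FALSE]
  key <- paste(feats$origin_id, feats$dest_id, sep = "\r")
  fkey <- paste(flows$origin_id, flows$dest_id, sep = "\r")
  mig <- numeric(nrow(feats))
  hit <- match(fkey, key)
  if (anyNA(hit)) {
    stop_slrmig("flow table contains pairs absent from the feature table")
  }
  mig[hit] <- flows$migrants
  outflow <- tapply(mig, feats$origin_id, sum)
  keep <- outflow[feats$origin_id] > 0
  feats <- feats[keep, , drop = FALSE]
  mig <- mig[keep]
  share <- mig / as.numeric(outflow[feats$origin_id])
  if (nrow(feats) == 0L) stop_slrmig("no origin with positive outflow")

  x <- ann_design(feats)
  center <- colMeans(x)
  scale_ <- apply(x, 2, stats::sd)
  scale_[scale_ == 0] <- 1
  xs <- scale(x, center = center, scale = scale_)

  origins <- unique(feats$origin_id)
  fit <- with_seed(seed, {
    n_hold <- if (length(origins) >= 5) floor(holdout * length(origins)) else 0
    hold <- if (n_hold > 0) sample(origins, n_hold) else character(0)
    is_val <- feats$origin_id %in% hold
    best <- NULL
    best_loss <- Inf
    for (r in seq_len(max(1L, restarts))) {
      net <- nnet::nnet(xs[!is_val, , drop = FALSE], share[!is_val],
                        size = hidden, decay = decay, maxit = maxit,
                        entropy = TRUE, trace = FALSE, MaxNWts = 10000)
      eval_idx <- if (any(is_val)) is_val else !is_val
      p <- as.numeric(stats::predict(net, xs[eval_idx, , drop = FALSE]))
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      y <- share[eval_idx]
      loss <- -mean(y * log(p) + (1 - y) * log(1 - p))
      if (loss < best_loss) {
        best_loss <- loss
        best <- net
      }
    }
    list(net = best, loss = best_loss, holdout_origins = hold)
  })

  structure(list(kind = "neural", net = fit$net, center = center,
                 scale = scale_, hidden = hidden, decay = decay,
                 maxit = maxit, seed = seed, loss = fit$loss,
                 holdout_origins = fit$holdout_origins,
                 n_train_pairs = sum(!feats$origin_id %in% fit$holdout_origins)),
            class = c("migration_ann", "migration_model"))
}

ann_design <- function(features) {
  cbind(log_mi = log(pmax(features$m_i, 1e-9)),
        log_mj = log(pmax(features$m_j, 1e-9)),
        log_d = log(pmax(features$d_km, 1e-9)),
        log_s = log1p(pmax(features$s_ij, 0)))
}

#' @export
model_weights.migration_ann <- function(object, features) {
  if (is.null(object$net)) stop_slrmig("model has not been fitted")
  x <- ann_design(features)
  xs <- scale(x, center = object$center, scale = object$scale)
  as.numeric(stats::predict(object$net, xs))
}

#' @export
print.migration_ann <- function(x, ...) {
  cat(sprintf(
    "Neural migration model: %d hidden units, decay %g, seed %d\n",
    x$hidden, x$decay, x$seed))
  cat(sprintf("  trained on %d pairs; selection cross-entropy %.4f\n",
              x$n_train_pairs, x$loss))
  invisible(x)
}

#' @export
coef.migration_ann <- function(object, ...) {
  object$net$wts
}

#' Save or restore a fitted neural migration model
#'
#' Serialises the model (hyperparameters, feature standardisation, and the
#' full weight vector at full precision) to a JSON file, and restores it to
#' a predictive object. A restored model reproduces predictions exactly.
#'
#' @param model a `migration_ann`.
#' @param path file path for the JSON model file.
#' @return `read_migration_ann` returns a `migration_ann`.
#' @export
write_migration_ann <- function(model, path) {
  stopifnot(inherits(model, "migration_ann"))
  payload <- list(kind = "neural", hidden = model$hidden, decay = model$decay,
                  maxit = model$maxit, seed = model$seed,
                  center = as.numeric(model$center),
                  scale = as.numeric(model$scale),
                  n_inputs = ncol(ann_design(data.frame(
                    m_i = 1, m_j = 1, d_km = 1, s_ij = 0))),
                  wts = model$net$wts)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_migration_ann
#' @export
read_migration_ann <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  # rebuild an nnet skeleton carrying the stored weights
  n_in <- p$n_inputs
  dummy_x <- matrix(stats::runif(4 * n_in), 4, n_in)
  net <- with_seed(1, nnet::nnet(dummy_x, c(0, 1, 0, 1), size = p$hidden,
                                 maxit = 1, entropy = TRUE, trace = FALSE,
                                 MaxNWts = 10000))
  stopifnot(length(net$wts) == length(p$wts))
  net$wts <- p$wts
  center <- p$center
  scale_ <- p$scale
  names(center) <- names(scale_) <- c("log_mi", "log_mj", "log_d", "log_s")
  structure(list(kind = "neural", net = net, center = center, scale = scale_,
                 hidden = p$hidden, decay = p$decay, maxit = p$maxit,
                 seed = p$seed, loss = NA_real_, holdout_origins = character(0),
                 n_train_pairs = NA_integer_),
            class = c("migration_ann", "migration_model"))
}
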