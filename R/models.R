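#' Spatial-interaction migration models
#'
#' Constructors for the interchangeable migration-probability models. Each
#' model maps a feature table (one row per origin-destination pair, see
#' [build_feature_table()]) to a conditional destination-choice probability
#' `P_ij` via [predict()]: nonnegative scores, normalised within each origin
#' so every origin's row sums to one over its allowed destination set.
#'
#' `radiation_model()` is the parameter-free intervening-opportunity model
#' with unnormalised weight
#' \deqn{w_{ij} = \frac{m_i m_j}{(m_i + s_{ij})(m_i + m_j + s_{ij})}.}
#'
#' `extended_radiation_model(alpha)` is its one-parameter generalisation,
#' \deqn{w_{ij} = \frac{[(m_i+m_j+s_{ij})^\alpha - (m_i+s_{ij})^\alpha]
#'   (m_i^\alpha + 1)}{[(m_i+s_{ij})^\alpha + 1]
#'   [(m_i+m_j+s_{ij})^\alpha + 1]},}
#' which improves fit across spatial scales; it approaches the radiation
#' model for large populations at `alpha = 1`.
#'
#' Row normalisation over the allowed destination set (rather than an
#' open-system correction) is used because the framework treats `P_ij` as a
#' distribution over where a leaving migrant goes.
#'
#' @param alpha positive scale exponent of the extended model.
#' @return an object of class `c(<kind>, "migration_model")`.
#' @seealso [fit_migration_ann()] for the trainable neural scorer,
#'   [predict.migration_model()].
#' @examples
#' feats <- data.frame(origin_id = "A", dest_id = c("B", "C"),
#'                     m_i = 100, m_j = 50, d_km = c(100, 200), s_ij = c(0, 50))
#' predict(radiation_model(), feats)  # c(2/3, 1/3)
#' @export
radiation_model <- function() {
  structure(list(kind = "radiation"),
            class = c("radiation_model", "migration_model"))
}

#' @rdname radiation_model
#' @export
extended_radiation_model <- function(alpha = 0.5) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0) {
    stop_slrmig("alpha must be a single positive number")
  }
  structure(list(kind = "extended_radiation", alpha = alpha),
            class = c("extended_radiation_model", "migration_model"))
}

#' Distance-decay migration model
#'
#' A simple gravity-flavoured scorer with weight
#' `w_ij = m_j * exp(-d_km / lambda)`: destination mass tilted towards
#' nearby zones. Used by the synthetic-data generator as a climate-flow
#' generator distinct from the radiation family, so that dual-model fitting
#' has a real signal to separate.
#'
#' @param lambda decay length in kilometres.
#' @export
distance_decay_model <- function(lambda = 200) {
  if (lambda <= 0) stop_slrmig("lambda must be positive")
  structure(list(kind = "distance_decay", lambda = lambda),
            class = c("distance_decay_model", "migration_model"))
}

#' Stipulated-probability migration model
#'
#' A migration model whose destination-choice weights are looked up from a
#' fixed table of (origin, destination, weight). Pairs absent from the table
#' get weight zero; rows are renormalised per origin as usual. Useful for
#' hand-specified worked examples and for replaying a previously computed
#' probability matrix.
#'
#' @param probs data.frame with columns `origin_id`, `dest_id`, `p`.
#' @export
table_model <- function(probs) {
  check_columns(probs, c("origin_id", "dest_id", "p"), "probability table")
  if (any(probs$p < 0)) stop_slrmig("stipulated weights must be nonnegative")
  structure(list(kind = "table",
                 key = paste(probs$origin_id, probs$dest_id, sep = "\r"),
                 p = probs$p),
            class = c("table_model", "migration_model"))
}

model_weights <- function(object, features) {
  UseMethod("model_weights")
}

#' @export
model_weights.table_model <- function(object, features) {
  key <- paste(features$origin_id, features$dest_id, sep = "\r")
  w <- object$p[match(key, object$key)]
  w[is.na(w)] <- 0
  w
}

#' @export
model_weights.radiation_model <- function(object, features) {
  with(features, m_i * m_j / ((m_i + s_ij) * (m_i + m_j + s_ij)))
}

#' @export
model_weights.extended_radiation_model <- function(object, features) {
  a <- object$alpha
  with(features, {
    ((m_i + m_j + s_ij)^a - (m_i + s_ij)^a) * (m_i^a + 1) /
      (((m_i + s_ij)^a + 1) * ((m_i + m_j + s_ij)^a + 1))
  })
}

#' @export
model_weights.distance_decay_model <- function(object, features) {
  with(features, m_j * exp(-d_km / object$lambda))
}

# Normalise nonnegative weights into per-origin probability rows. Origins
# whose weights sum to zero (e.g. all destination populations zero) fall
# back to a uniform row, with a warning.
row_normalize <- function(w, origin) {
  w[!is.finite(w)] <- 0
  w <- pmax(w, 0)
  origin <- as.character(origin)
  totals <- tapply(w, origin, sum)
  tot_i <- as.numeric(totals[origin])
  zero <- tot_i == 0
  if (any(zero)) {
    warning("zero total weight for origin(s) ",
            paste(unique(origin[zero]), collapse = ", "),
            "; using a uniform row", call. = FALSE)
    counts <- tapply(rep(1, length(w)), origin, sum)
    w[zero] <- 1
    tot_i[zero] <- as.numeric(counts[origin[zero]])
  }
  w / tot_i
}

#' Predict destination-choice probabilities
#'
#' Evaluates a migration model on a feature table and returns the
#' probability `P_ij` for each row, normalised within each `origin_id` group
#' so each origin's probabilities sum to one.
#'
#' @param object a `migration_model`.
#' @param features feature table from [build_feature_table()].
#' @param ... unused.
#' @return numeric vector aligned with `features` rows.
#' @export
predict.migration_model <- function(object, features, ...) {
  check_columns(features, c("origin_id", "m_i", "m_j", "s_ij"),
                "feature table")
  row_normalize(model_weights(object, features), features$origin_id)
}

#' @export
print.migration_model <- function(x, ...) {
  cat("Migration model:", x$kind)
  if (!is.null(x$alpha)) cat(sprintf(" (alpha = %g)", x$alpha))
  if (!is.null(x$lambda)) cat(sprintf(" (lambda = %g km)", x$lambda))
  cat("\n")
  invisible(x)
}

#' Production function
#'
#' The number of migrants leaving a zone as a linear fraction of its
#' population, `g(m) = rate * m`. The climate production is the identity
#' (`rate = 1`): everyone on flooded land must move. The business-as-usual
#' production defaults to `rate = 0.03`, the observed fraction of a county's
#' population migrating in a normal year.
#'
#' @param rate fraction in `[0, 1]`.
#' @return a function of class `production_function`.
#' @examples
#' g_S <- production_function(0.03)
#' g_S(1000)  # 30
#' @export
production_function <- function(rate) {
  if (!is.numeric(rate) || length(rate) != 1L || rate < 0 || rate > 1) {
    stop_slrmig("rate must be a single number in [0, 1]")
  }
  f <- function(m) {
    if (any(m < 0)) stop_slrmig("population must be nonnegative")
    rate * m
  }
  structure(f, rate = rate, class = c("production_function", "function"))
}

#' Common part of commuters (CPC)
#'
#' Similarity between two flow matrices:
#' `2 * sum(min(T_a, T_b)) / (sum(T_a) + sum(T_b))`. Equals 1 iff the
#' matrices are identical and 0 iff their supports are disjoint. Matrices
#' are given in sparse long form (`origin_id`, `dest_id`, `flow`); missing
#' pairs are zeros.
#'
#' @param a,b flow tables with columns `origin_id`, `dest_id` and `flow`
#'   (or `migrants`).
#' @return a score in `[0, 1]`.
#' @export
cpc <- function(a, b) {
  norm <- function(x) {
    x <- as.data.frame(x)
    fcol <- intersect(c("flow", "migrants"), names(x))[1L]
    if (is.na(fcol)) stop_slrmig("flow table needs a 'flow' or 'migrants' column")
    data.frame(key = paste(x$origin_id, x$dest_id, sep = "\r"),
               flow = as.numeric(x[[fcol]]), stringsAsFactors = FALSE)
  }
  a <- norm(a)
  b <- norm(b)
  ta <- sum(a$flow)
  tb <- sum(b$flow)
  if (ta == 0 && tb == 0) stop_slrmig("CPC undefined: both matrices are all-zero")
  keys <- union(a$key, b$key)
  va <- vb <- numeric(length(keys))
  sa <- rowsum(a$flow, a$key)  # duplicate keys (e.g. climate + bau on the
  sb <- rowsum(b$flow, b$key)  # same pair) are summed before comparison
  va[match(rownames(sa), keys)] <- sa[, 1L]
  vb[match(rownames(sb), keys)] <- sb[, 1L]
  2 * sum(pmin(va, vb)) / (ta + tb)
}
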