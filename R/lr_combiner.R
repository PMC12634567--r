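## lr_combiner: logistic regression over shape and sequence similarity.

#' Construct a logistic-regression combiner model
#'
#' The model predicts the probability that a TCR pair shares specificity
#' from its fingerprint similarity and its sequence similarity:
#' `p = 1 / (1 + exp(-(b0 + W_fp * fp_sim + W_seq * seq_sim)))`.
#' `feature_order` states explicitly which published weight multiplies which
#' score, so either convention can be loaded.
#'
#' @param b0 bias term.
#' @param w_fp weight of the fingerprint similarity.
#' @param w_seq weight of the sequence similarity.
#' @param threshold classifier probability cutoff in (0, 1); pairs with
#'   `p > threshold` are called same-specificity.
#' @return object of class `lr_model`.
#' @export
lr_model <- function(b0, w_fp, w_seq, threshold = 0.5) {
  stopifnot(is.finite(b0), is.finite(w_fp), is.finite(w_seq),
            threshold > 0, threshold < 1)
  structure(list(b0 = b0, w_fp = w_fp, w_seq = w_seq,
                 feature_order = c("fp_sim", "seq_sim"),
                 threshold = threshold),
            class = "lr_model")
}

#' Published combiner coefficients
#'
#' The reported best model: bias -4.4545 with weights 7.3739 and 0.5752 and
#' a 0.5 classifier threshold. The larger weight is bound to the sequence
#' similarity, reflecting that the sequence term was reported to contribute
#' more to the prediction; pass `larger_weight = "fp"` for the opposite
#' binding.
#'
#' @param larger_weight which feature carries the 7.3739 weight
#'   (`"seq"`, default, or `"fp"`).
#' @return an [lr_model()].
#' @export
published_lr_model <- function(larger_weight = c("seq", "fp")) {
  larger_weight <- match.arg(larger_weight)
  if (larger_weight == "seq") {
    lr_model(b0 = -4.4545, w_fp = 0.5752, w_seq = 7.3739)
  } else {
    lr_model(b0 = -4.4545, w_fp = 7.3739, w_seq = 0.5752)
  }
}

#' Same-specificity probability of a TCR pair
#'
#' @param model an [lr_model()].
#' @param fp_sim fingerprint similarity in [0, 1] (vectorized).
#' @param seq_sim sequence similarity in [0, 1] (vectorized).
#' @return probability in (0, 1); attribute-free numeric vector.
#' @export
predict_probability <- function(model, fp_sim, seq_sim) {
  stopifnot(inherits(model, "lr_model"))
  if (any(fp_sim < 0 | fp_sim > 1) || any(seq_sim < 0 | seq_sim > 1)) {
    stop("similarity scores must lie in [0, 1]")
  }
  eta <- model$b0 + model$w_fp * fp_sim + model$w_seq * seq_sim
  1 / (1 + exp(-eta))
}

#' Classify TCR pairs as same-specificity
#'
#' @inheritParams predict_probability
#' @return logical vector: `p > threshold`.
#' @export
classify_pairs <- function(model, fp_sim, seq_sim) {
  predict_probability(model, fp_sim, seq_sim) > model$threshold
}

#' Fit the combiner by maximum likelihood
#'
#' Fits the logistic regression on labeled TCR pairs with `stats::glm`
#' (binomial family). If the classes are perfectly separable the
#' unregularized MLE diverges; a weak L2 penalty is then applied and a
#' warning raised so the returned coefficients stay finite.
#'
#' @param pairs data frame with columns `fp_sim`, `seq_sim` and logical (or
#'   0/1) `same_peptide`; both classes must be present.
#' @param threshold classifier cutoff stored on the returned model.
#' @param ridge L2 penalty used only in the separable fallback.
#' @return an [lr_model()] with extra fields `fit` (coefficient summary
#'   table or `NULL`), `converged` and `log_likelihood`.
#' @export
fit_lr <- function(pairs, threshold = 0.5, ridge = 1e-4) {
  need <- c("fp_sim", "seq_sim", "same_peptide")
  if (!all(need %in% names(pairs))) {
    stop("pairs must have columns: ", paste(need, collapse = ", "))
  }
  y <- as.integer(as.logical(pairs$same_peptide))
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (stats::var(pairs$fp_sim) == 0 && stats::var(pairs$seq_sim) == 0) {
    stop("constant features: model not identifiable")
  }
  separable <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ fp_sim + seq_sim, family = stats::binomial(),
               data = pairs),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        separable <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (separable || !fit$converged || any(abs(stats::coef(fit)) > 50)) {
    warning("(quasi-)separable pairs: applying weak L2 regularization")
    X <- cbind(1, pairs$fp_sim, pairs$seq_sim)
    nll <- function(b) {
      eta <- X %*% b
      sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) +
        ridge * sum(b[-1]^2)
    }
    opt <- stats::optim(c(0, 0, 0), nll, method = "BFGS",
                        control = list(maxit = 1000))
    cf <- opt$par
    model <- lr_model(cf[1], cf[2], cf[3], threshold)
    model$fit <- NULL
    model$converged <- opt$convergence == 0
    model$log_likelihood <- -(opt$value - ridge * sum(cf[-1]^2))
    return(model)
  }
  cf <- stats::coef(fit)
  model <- lr_model(cf[["(Intercept)"]], cf[["fp_sim"]], cf[["seq_sim"]],
                    threshold)
  model$fit <- stats::coef(summary(fit))
  model$converged <- fit$converged
  model$log_likelihood <- as.numeric(stats::logLik(fit))
  model
}

#' Log-likelihood of a model on labeled pairs
#'
#' @param model an [lr_model()].
#' @param pairs as in [fit_lr()].
#' @return total Bernoulli log-likelihood.
#' @export
lr_log_likelihood <- function(model, pairs) {
  y <- as.integer(as.logical(pairs$same_peptide))
  p <- predict_probability(model, pairs$fp_sim, pairs$seq_sim)
  sum(y * log(p) + (1 - y) * log1p(-p))
}

#' Write / read a combiner model as JSON text
#'
#' @param model an [lr_model()].
#' @param path file path.
#' @export
write_lr_model <- function(model, path) {
  stopifnot(inherits(model, "lr_model"))
  jsonlite::write_json(
    list(b0 = model$b0, w_fp = model$w_fp, w_seq = model$w_seq,
         feature_order = model$feature_order, threshold = model$threshold),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_lr_model
#' @export
read_lr_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- lr_model(x$b0, x$w_fp, x$w_seq, x$threshold)
  if (!is.null(x$feature_order)) m$feature_order <- x$feature_order
  m
}
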