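#' Normalise a production measurement to a reference
#'
#' Production rates are expressed as a percentage of a fixed reference
#' construct (set at 100%); rates above 100% are expected for variants that
#' out-produce the reference.
#'
#' @param raw_quantity Measured quantity (e.g. ug/ml).
#' @param reference_quantity Reference quantity in the same units (> 0).
#' @return Rate in percent.
#' @export
normalize_rate <- function(raw_quantity, reference_quantity) {
  if (any(reference_quantity <= 0)) stop("reference quantity must be positive")
  100 * raw_quantity / reference_quantity
}

#' Categorise a production rate
#'
#' Maps a normalised rate (%) into three ordinal classes: low (< `low_cut`),
#' medium (`low_cut` to `high_cut`, both boundaries inclusive), high
#' (> `high_cut`). Defaults are the 20% / 70% cuts.
#'
#' @param rate Numeric vector of rates in percent; must be finite and >= 0.
#' @param low_cut,high_cut Class boundaries in percent, `0 < low_cut <
#'   high_cut`.
#' @return Integer vector with values 0 (low), 1 (medium), 2 (high).
#' @export
#' @examples
#' categorize(c(19.99, 20, 70, 70.01))
categorize <- function(rate, low_cut = 20, high_cut = 70) {
  stopifnot(low_cut > 0, low_cut < high_cut)
  if (any(!is.finite(rate)) || any(rate < 0)) {
    stop("rates must be finite and non-negative")
  }
  ifelse(rate < low_cut, 0L, ifelse(rate <= high_cut, 1L, 2L))
}

# ---- penalized one-vs-rest logistic core --------------------------------

sigmoid <- function(z) 1 / (1 + exp(-z))

# Numerically safe log(1 + exp(z))
log1pexp <- function(z) ifelse(z > 30, z, log1p(exp(z)))

# Newton-Raphson with step halving on the weighted, L2-penalised binomial
# negative log-likelihood. The intercept is unpenalised. Converges when the
# max-abs gradient drops to `tol` or after `max_iter` iterations. Returns
# intercept, coefficients and the objective trace (used to verify monotone
# descent).
fit_penalized_logistic <- function(X, y, lambda, weights = rep(1, length(y)),
                                   max_iter = 1000, tol = 1e-6) {
  n <- nrow(X); p <- ncol(X)
  Xa <- cbind(`(Intercept)` = 1, X)
  pen <- c(0, rep(lambda, p))
  beta <- numeric(p + 1)
  obj <- function(b) {
    eta <- drop(Xa %*% b)
    sum(weights * (log1pexp(eta) - y * eta)) + 0.5 * sum(pen * b^2)
  }
  trace <- obj(beta)
  for (it in seq_len(max_iter)) {
    eta <- drop(Xa %*% beta)
    mu <- sigmoid(eta)
    g <- drop(crossprod(Xa, weights * (mu - y))) + pen * beta
    if (max(abs(g)) <= tol) break
    w <- pmax(weights * mu * (1 - mu), 1e-10)
    H <- crossprod(Xa * sqrt(w)) + diag(pen + 1e-12, p + 1)
    step <- tryCatch(solve(H, g),
                     error = function(e) solve(H + diag(1e-6, p + 1), g))
    f0 <- trace[length(trace)]
    t <- 1
    improved <- FALSE
    while (t >= 1e-10) {
      cand <- beta - t * step
      f1 <- obj(cand)
      if (f1 <= f0) { improved <- TRUE; break }
      t <- t / 2
    }
    if (!improved) break  # no descent direction left at machine precision
    beta <- cand
    trace <- c(trace, f1)
    if (f0 - f1 < 1e-12 && max(abs(g)) < 1e-4) break
  }
  list(intercept = unname(beta[1]), coef = beta[-1],
       objective_trace = trace, iterations = length(trace) - 1)
}

# z-score parameters from a training matrix; constant columns get scale 1 so
# standardisation never divides by zero.
standardizer <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale)
}

apply_standardizer <- function(X, std) {
  sweep(sweep(X, 2, std$center, "-"), 2, std$scale, "/")
}

# Extract the 20-column count matrix, in alphabetical amino-acid order, from
# a variant records data frame.
feature_matrix <- function(records) {
  cols <- aa_alphabet()
  missing <- setdiff(cols, names(records))
  if (length(missing) > 0) {
    stop("records lack amino-acid count columns: ",
         paste(missing, collapse = ", "))
  }
  X <- as.matrix(records[, cols])
  if (any(!is.finite(X)) || any(X < 0)) {
    stop("count features must be finite and non-negative")
  }
  X
}

record_labels <- function(records, low_cut = 20, high_cut = 70) {
  if ("label" %in% names(records)) return(as.integer(records$label))
  categorize(records$production_rate, low_cut, high_cut)
}

# ---- model fitting -------------------------------------------------------

#' Fit the three-class production-rate predictor
#'
#' One-vs-rest L2-regularised logistic regression over amino-acid count
#' features. The regularisation strength is tuned by k-fold cross-validation
#' on the model set (default 20 folds, i.e. ~95% train / 5% validation per
#' cycle), scoring each candidate by mean weighted precision over the
#' validation folds; the final model is refit on all records at the selected
#' strength. Features are z-scored on the training portion only; class
#' weights (default inverse class frequency) multiply the per-sample
#' log-likelihood terms to counter class imbalance. Per-class fits use a
#' damped Newton method run to gradient-norm tolerance 1e-6 or `max_iter`
#' iterations.
#'
#' @param records Data frame with the 20 amino-acid count columns (A..Y) and
#'   `production_rate` (or a precomputed integer `label` column).
#' @param lambda_grid Candidate L2 strengths; default 10 values log-spaced
#'   from 1e-4 to 1e4.
#' @param folds Number of cross-validation folds.
#' @param max_iter Optimiser iteration cap per fit.
#' @param class_weights Optional named/numeric length-3 vector of per-class
#'   weights; default inverse class frequency normalised to mean 1.
#' @param seed Integer seed governing fold assignment.
#' @param low_cut,high_cut Rate thresholds used when labels are derived.
#' @return Object of class `aacap_model`: intercepts (length 3),
#'   coefficient matrix (3 x 20), selected `lambda`, standardisation
#'   parameters, the CV score table, and fitting metadata.
#' @export
fit_production_model <- function(records,
                                 lambda_grid = 10^seq(-4, 4, length.out = 10),
                                 folds = 20, max_iter = 1000,
                                 class_weights = NULL, seed = 1L,
                                 low_cut = 20, high_cut = 70) {
  X <- feature_matrix(records)
  y <- record_labels(records, low_cut, high_cut)
  n <- nrow(X)
  classes <- 0:2
  present <- sort(unique(y))
  if (length(present) < 2) stop("need at least 2 classes to fit")

  if (is.null(class_weights)) {
    freq <- as.numeric(table(factor(y, levels = classes)))
    cw <- ifelse(freq > 0, 1 / freq, 0)
    cw <- cw / mean(cw[cw > 0])
  } else {
    stopifnot(length(class_weights) == 3)
    cw <- as.numeric(class_weights)
  }
  names(cw) <- as.character(classes)
  sample_w <- cw[as.character(y)]

  fit_all_classes <- function(Xs, yy, ww, lambda) {
    lapply(classes, function(k) {
      fit_penalized_logistic(Xs, as.numeric(yy == k), lambda, ww,
                             max_iter = max_iter)
    })
  }

  # -- lambda selection by k-fold CV on weighted precision
  set.seed(seed)
  fold_id <- sample(rep(seq_len(folds), length.out = n))
  cv_scores <- matrix(NA_real_, nrow = length(lambda_grid), ncol = folds)
  for (li in seq_along(lambda_grid)) {
    lambda <- lambda_grid[li]
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      if (length(unique(y[tr])) < length(present)) {
        warning(sprintf("fold %d lacks a class in training; fold skipped", f))
        next
      }
      std <- standardizer(X[tr, , drop = FALSE])
      Xtr <- apply_standardizer(X[tr, , drop = FALSE], std)
      Xva <- apply_standardizer(X[!tr, , drop = FALSE], std)
      fits <- fit_all_classes(Xtr, y[tr], sample_w[tr], lambda)
      scores <- sapply(fits, function(fk) {
        sigmoid(fk$intercept + drop(Xva %*% fk$coef))
      })
      scores <- matrix(scores, ncol = 3)
      pred <- classes[max.col(scores, ties.method = "first")]
      cv_scores[li, f] <- weighted_precision(y[!tr], pred)
    }
  }
  mean_scores <- rowMeans(cv_scores, na.rm = TRUE)
  if (all(!is.finite(mean_scores))) stop("all cross-validation folds were skipped")
  best <- which(mean_scores == max(mean_scores, na.rm = TRUE))[1]
  lambda_hat <- lambda_grid[best]

  # -- refit on the full model set at the selected strength
  std <- standardizer(X)
  Xs <- apply_standardizer(X, std)
  fits <- fit_all_classes(Xs, y, sample_w, lambda_hat)

  structure(
    list(
      classes    = classes,
      intercepts = vapply(fits, `[[`, numeric(1), "intercept"),
      coef       = t(vapply(fits, `[[`, numeric(20), "coef")),
      lambda     = lambda_hat,
      center     = std$center,
      scale      = std$scale,
      cv         = data.frame(lambda = lambda_grid,
                              mean_weighted_precision = mean_scores),
      class_weights = cw,
      objective_traces = lapply(fits, `[[`, "objective_trace"),
      folds = folds, max_iter = max_iter, seed = seed,
      low_cut = low_cut, high_cut = high_cut
    ),
    class = "aacap_model"
  )
}

#' @export
print.aacap_model <- function(x, ...) {
  cat("One-vs-rest L2 logistic production-rate model\n")
  cat(sprintf("  lambda = %g (chosen by %d-fold CV, weighted precision %.3f)\n",
              x$lambda, x$folds,
              max(x$cv$mean_weighted_precision, na.rm = TRUE)))
  cat("  intercepts:", sprintf("%.3f", x$intercepts), "\n")
  invisible(x)
}

#' Per-class probabilities from the printed one-vs-rest equation
#'
#' Each class score is the sigmoid of its affine predictor,
#' `1 / (1 + exp(-(b0_k + b_k . x)))`, evaluated per class — not a softmax.
#' Because one-vs-rest scores need not sum to one, a normalised view
#' (scores divided by their sum) is available for ranking metrics.
#'
#' @param model An `aacap_model`.
#' @param x Numeric feature vector of length 20, or a matrix/data frame of
#'   rows of features (raw counts; standardisation is applied internally).
#' @param normalized Divide each row of scores by its sum.
#' @return Numeric matrix (rows = samples) with one column per class.
#' @export
class_probability <- function(model, x, normalized = FALSE) {
  stopifnot(inherits(model, "aacap_model"))
  if (is.data.frame(x)) x <- feature_matrix(x)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != ncol(model$coef)) {
    stop(sprintf("feature dimension %d does not match model dimension %d",
                 ncol(x), ncol(model$coef)))
  }
  Xs <- apply_standardizer(x, list(center = model$center, scale = model$scale))
  eta <- sweep(Xs %*% t(model$coef), 2, model$intercepts, "+")
  p <- sigmoid(eta)
  colnames(p) <- as.character(model$classes)
  if (normalized) p <- p / rowSums(p)
  p
}

#' Predict production-rate classes
#'
#' Argmax over the one-vs-rest class scores; ties break towards the lower
#' class index, so repeated runs are deterministic.
#'
#' @param object An `aacap_model`.
#' @param newdata Feature vector, matrix, or records data frame.
#' @param ... Unused.
#' @return Integer vector of class labels (0, 1, 2).
#' @export
predict.aacap_model <- function(object, newdata, ...) {
  p <- class_probability(object, newdata)
  object$classes[max.col(p, ties.method = "first")]
}

#' Serialise a fitted model to JSON
#'
#' @param model An `aacap_model`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "aacap_model"))
  obj <- list(
    classes = model$classes, intercepts = model$intercepts,
    coefficients = as.data.frame(model$coef),
    lambda = model$lambda,
    standardization = list(center = as.list(model$center),
                           scale = as.list(model$scale)),
    class_weights = as.list(model$class_weights),
    folds = model$folds, max_iter = model$max_iter, seed = model$seed
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# ---- metrics -------------------------------------------------------------

#' Support-weighted precision
#'
#' `sum_k (support_k / N) * precision_k` over the classes present in
#' `y_true`. A class that is never predicted contributes precision 0 (a
#' warning notes it).
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @return Score in \[0, 1\].
#' @export
weighted_precision <- function(y_true, y_pred) {
  check_metric_input(y_true, y_pred)
  per_class_scores(y_true, y_pred, "precision")
}

#' Support-weighted F1 score
#'
#' Per-class F1 (harmonic mean of precision and recall, 0 when undefined),
#' averaged with weights proportional to class support in `y_true`.
#'
#' @inheritParams weighted_precision
#' @return Score in \[0, 1\].
#' @export
weighted_f1 <- function(y_true, y_pred) {
  check_metric_input(y_true, y_pred)
  per_class_scores(y_true, y_pred, "f1")
}

check_metric_input <- function(y_true, y_pred) {
  if (length(y_true) == 0) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("y_true and y_pred lengths differ")
}

per_class_scores <- function(y_true, y_pred, what) {
  classes <- sort(unique(y_true))
  n <- length(y_true)
  total <- 0
  for (k in classes) {
    support <- sum(y_true == k)
    tp <- sum(y_true == k & y_pred == k)
    predicted <- sum(y_pred == k)
    if (predicted == 0) {
      warning(sprintf("class %s never predicted; precision taken as 0", k))
      prec <- 0
    } else {
      prec <- tp / predicted
    }
    score <- if (what == "precision") {
      prec
    } else {
      rec <- tp / support
      if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    }
    total <- total + support / n * score
  }
  total
}

#' Mean pairwise ROC AUC
#'
#' Multiclass discrimination summary: for every unordered class pair (j, k),
#' restrict to samples of those two classes and compute the two-class AUC of
#' the class-k score (Mann-Whitney rank form, ties counted 0.5) and of the
#' class-j score, average the two directions, then average over all pairs.
#'
#' @param y_true Label vector with at least two classes.
#' @param class_scores Matrix of per-class scores, columns named by class
#'   (or in `0:2` order).
#' @return Score in \[0, 1\].
#' @export
pairwise_auc <- function(y_true, class_scores) {
  if (length(y_true) == 0) stop("empty input")
  class_scores <- as.matrix(class_scores)
  classes <- sort(unique(y_true))
  if (length(classes) < 2) stop("pairwise AUC needs at least 2 classes")
  col_for <- function(k) {
    nm <- as.character(k)
    if (!is.null(colnames(class_scores)) && nm %in% colnames(class_scores)) {
      class_scores[, nm]
    } else {
      class_scores[, match(k, classes)]
    }
  }
  pair_vals <- c()
  combos <- utils::combn(classes, 2)
  for (ci in seq_len(ncol(combos))) {
    j <- combos[1, ci]; k <- combos[2, ci]
    idx <- y_true %in% c(j, k)
    a_jk <- binary_auc(col_for(k)[idx], y_true[idx] == k)
    a_kj <- binary_auc(col_for(j)[idx], y_true[idx] == j)
    pair_vals <- c(pair_vals, (a_jk + a_kj) / 2)
  }
  mean(pair_vals)
}

# Rank/Mann-Whitney two-class AUC; ties contribute 0.5.
binary_auc <- function(score, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) stop("binary AUC needs both classes")
  r <- rank(score, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# ---- protocol ------------------------------------------------------------

#' Partition records into model and test sets
#'
#' Uniform random disjoint partition into the model set M and two held-out
#' test sets T_a and T_b. Default sizes are (118, 30, 20) at N = 168; for
#' other N the sizes are scaled proportionally (largest-remainder rounding).
#'
#' @param n Number of records.
#' @param sizes Length-3 sizes for (M, T_a, T_b) at the reference N = 168.
#' @param seed Integer seed; the same seed reproduces the same partition.
#' @return List of integer index vectors `M`, `T_a`, `T_b`.
#' @export
split_plan <- function(n, sizes = c(118, 30, 20), seed = 1L) {
  stopifnot(length(sizes) == 3, all(sizes > 0), n >= 3)
  ref <- sum(sizes)
  if (n != ref) {
    quota <- n * sizes / ref
    base <- floor(quota)
    rem <- n - sum(base)
    if (rem > 0) {
      extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1
    }
    sizes <- base
  }
  if (sum(sizes) != n) stop("split sizes are inconsistent with n")
  set.seed(seed)
  perm <- sample.int(n)
  list(
    M   = sort(perm[seq_len(sizes[1])]),
    T_a = sort(perm[sizes[1] + seq_len(sizes[2])]),
    T_b = sort(perm[sizes[1] + sizes[2] + seq_len(sizes[3])])
  )
}

#' Frequency-based baseline classifier
#'
#' Baseline control matching a stratified dummy classifier: class scores are
#' the training class priors (constant across samples, so its pairwise AUC
#' is 0.5 by construction) and predicted labels are sampled from the priors.
#' `method = "most_frequent"` predicts the modal class instead.
#'
#' @param records Training records data frame.
#' @param seed Seed for the stratified sampling of predictions.
#' @param method `"stratified"` (default) or `"most_frequent"`.
#' @param low_cut,high_cut Rate thresholds used when labels are derived.
#' @return Object of class `aacap_dummy` with the training priors.
#' @export
dummy_baseline <- function(records, seed = 1L, method = c("stratified",
                                                          "most_frequent"),
                           low_cut = 20, high_cut = 70) {
  method <- match.arg(method)
  y <- record_labels(records, low_cut, high_cut)
  priors <- as.numeric(table(factor(y, levels = 0:2))) / length(y)
  structure(list(priors = stats::setNames(priors, as.character(0:2)),
                 method = method, seed = seed),
            class = "aacap_dummy")
}

#' @export
predict.aacap_dummy <- function(object, newdata, ...) {
  n <- if (is.data.frame(newdata) || is.matrix(newdata)) nrow(newdata) else newdata
  if (object$method == "most_frequent") {
    return(rep((0:2)[which.max(object$priors)], n))
  }
  set.seed(object$seed)
  sample(0:2, n, replace = TRUE, prob = object$priors)
}

dummy_scores <- function(object, n) {
  matrix(object$priors, nrow = n, ncol = 3, byrow = TRUE,
         dimnames = list(NULL, as.character(0:2)))
}

#' Evaluate a fitted model on a test set
#'
#' @param model An `aacap_model` or `aacap_dummy`.
#' @param records Test records data frame.
#' @param low_cut,high_cut Rate thresholds used when labels are derived.
#' @return List with `pairwise_auc`, `weighted_f1`, `weighted_precision`,
#'   `per_class` (precision/recall per class), and `n`.
#' @export
evaluate_model <- function(model, records, low_cut = 20, high_cut = 70) {
  y <- record_labels(records, low_cut, high_cut)
  if (inherits(model, "aacap_dummy")) {
    scores <- dummy_scores(model, length(y))
    pred <- predict(model, length(y))
  } else {
    scores <- class_probability(model, records, normalized = TRUE)
    pred <- predict(model, records)
  }
  per_class <- lapply(sort(unique(y)), function(k) {
    tp <- sum(y == k & pred == k)
    list(class = k,
         precision = if (sum(pred == k) == 0) 0 else tp / sum(pred == k),
         recall = tp / sum(y == k),
         support = sum(y == k))
  })
  auc <- if (length(unique(y)) >= 2) pairwise_auc(y, scores) else NA_real_
  list(
    pairwise_auc       = auc,
    weighted_f1        = suppressWarnings(weighted_f1(y, pred)),
    weighted_precision = suppressWarnings(weighted_precision(y, pred)),
    per_class          = per_class,
    n                  = length(y)
  )
}

#' Triplicate train/test protocol
#'
#' For each replicate: draw a fresh (M, T_a, T_b) partition, fit the model
#' on M, evaluate it and the frequency baseline on both test sets.
#' Replicate seeds advance deterministically from `base_seed`, so the whole
#' run is bit-reproducible.
#'
#' @param records Full labelled dataset.
#' @param n_replicates Number of replicates (default 3).
#' @param base_seed Integer base seed.
#' @param sizes Reference split sizes, see [split_plan()].
#' @param ... Passed to [fit_production_model()].
#' @return List of replicates; each holds `seed`, `split`, `model`, and an
#'   evaluation report per test set for the model and the baseline.
#' @export
run_replicates <- function(records, n_replicates = 3, base_seed = 1L,
                           sizes = c(118, 30, 20), ...) {
  stopifnot(n_replicates >= 1)
  lapply(seq_len(n_replicates), function(r) {
    seed_r <- as.integer(base_seed + r - 1)
    plan <- split_plan(nrow(records), sizes = sizes, seed = seed_r)
    M <- records[plan$M, , drop = FALSE]
    model <- fit_production_model(M, seed = seed_r, ...)
    dummy <- dummy_baseline(M, seed = seed_r)
    reports <- lapply(list(T_a = plan$T_a, T_b = plan$T_b), function(idx) {
      test <- records[idx, , drop = FALSE]
      list(model = evaluate_model(model, test),
           baseline = evaluate_model(dummy, test))
    })
    list(replicate = r, seed = seed_r, split = plan, model = model,
         reports = reports)
  })
}

#' Write replicate evaluation reports as JSON
#'
#' Per-replicate blocks plus aggregate means over replicates and test sets.
#'
#' @param replicates Output of [run_replicates()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_eval_json <- function(replicates, path) {
  pull <- function(who, metric) {
    unlist(lapply(replicates, function(rep) {
      vapply(rep$reports, function(r) r[[who]][[metric]], numeric(1))
    }))
  }
  obj <- list(
    replicates = lapply(replicates, function(rep) {
      list(replicate = rep$replicate, seed = rep$seed,
           lambda = rep$model$lambda,
           reports = rep$reports)
    }),
    aggregate = list(
      model = list(mean_pairwise_auc = mean(pull("model", "pairwise_auc")),
                   mean_weighted_f1 = mean(pull("model", "weighted_f1"))),
      baseline = list(mean_pairwise_auc = mean(pull("baseline", "pairwise_auc")),
                      mean_weighted_f1 = mean(pull("baseline", "weighted_f1")))
    )
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
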