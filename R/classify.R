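# Marker-trained SVM localization prediction with macro-F1 model
# selection, plus the QSep map-resolution metric.
#
# The RBF kernel is parameterized as exp(-sigma * ||x - y||^2), i.e. the
# "sigma" of the hyperparameter grid maps directly onto e1071's `gamma`.
#
# The SVM score of a protein is the maximum per-class membership
# probability obtained by Platt-style pairwise coupling of the one-vs-one
# decision values: each binary decision value is passed through a sigmoid
# whose scale is fixed by the typical (median absolute) decision value of
# that pair's own training markers, and the resulting pairwise
# probabilities are coupled into class probabilities by the Wu-Lin
# quadratic method. Fixing the sigmoid scale this way keeps the score
# stable on cleanly separated training clusters, where per-problem
# sigmoid fitting is ill-conditioned. Predictions scoring below the
# classification threshold are labeled "unknown".

#' Macro F1 score from a confusion matrix
#'
#' Unweighted mean over classes of `2PR/(P+R)`. A class with neither
#' truths nor predictions is excluded; a class with truths but no correct
#' predictions contributes F1 = 0.
#'
#' @param confusion square count matrix, rows = true class, columns =
#'   predicted class, identical dimnames.
#' @return macro F1 in `[0, 1]`.
#' @export
macro_f1 <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == ncol(confusion))
  if (sum(confusion) == 0) stop("all-zero confusion matrix")
  truths <- rowSums(confusion)
  preds <- colSums(confusion)
  correct <- diag(confusion)
  active <- truths > 0 | preds > 0
  f1 <- vapply(which(active), function(k) {
    if (correct[k] == 0) return(0)
    p <- correct[k] / preds[k]
    r <- correct[k] / truths[k]
    2 * p * r / (p + r)
  }, 1.0)
  mean(f1)
}

#' Hyperparameter grid for SVM model selection
#'
#' Defaults follow the standard protocol for marker-based localization
#' classifiers: cost 20..60 in steps of two, sigma 0.01..100 in powers of
#' ten, each grid point scored by 100 repeated stratified 80/20 splits,
#' and a final 5-fold cross-validation of the chosen point.
#'
#' @param cost,sigma numeric grids.
#' @param inner_reps repeated stratified splits per grid point.
#' @param outer_folds folds of the final cross-validation.
#' @param train_fraction training share of each inner split.
#' @return a `svm_grid` list.
#' @export
svm_grid <- function(cost = seq(20, 60, by = 2),
                     sigma = c(0.01, 0.1, 1, 10, 100),
                     inner_reps = 100, outer_folds = 5,
                     train_fraction = 0.8) {
  stopifnot(length(cost) >= 1, length(sigma) >= 1,
            train_fraction > 0, train_fraction < 1,
            inner_reps >= 1, outer_folds >= 2)
  structure(list(cost = cost, sigma = sigma, inner_reps = inner_reps,
                 outer_folds = outer_folds,
                 train_fraction = train_fraction), class = "svm_grid")
}

.profiles_of <- function(x) {
  if (inherits(x, "profile_matrix")) x$intensities
  else if (inherits(x, "classified_map")) x$profiles
  else as.matrix(x)
}

# marker profiles + labels present in a map
.marker_training <- function(profiles, markers) {
  acc <- intersect(names(markers$entries), rownames(profiles))
  if (!length(acc)) stop("no marker proteins found in the map")
  labels <- factor(markers$entries[acc], levels = markers$taxonomy)
  list(x = profiles[acc, , drop = FALSE], y = labels, accession = acc)
}

.fit_svm <- function(x, y, cost, sigma, probability = TRUE) {
  e1071::svm(x, y, type = "C-classification", kernel = "radial",
             gamma = sigma, cost = cost, probability = probability,
             scale = FALSE)
}

# confusion matrix over the full taxonomy
.confusion <- function(truth, pred, levels) {
  table(factor(truth, levels = levels), factor(pred, levels = levels))
}

#' Tune SVM hyperparameters by repeated stratified splits
#'
#' Every `(cost, sigma)` grid point is scored by the mean macro F1 over
#' repeated stratified train/test splits of the marker proteins; the best
#' point (ties broken toward lowest cost, then lowest sigma — preferring
#' smoother models) is then assessed by a stratified k-fold
#' cross-validation over all markers.
#'
#' @param map a `profile_matrix`, matrix, or `classified_map` holding the
#'   profiles.
#' @param markers a [marker_set()].
#' @param grid an [svm_grid()].
#' @param seed integer seed.
#' @return list with `cost`, `sigma`, `cv_macro_f1` (final k-fold score)
#'   and `grid_scores` (data frame of mean inner macro F1 per point).
#' @export
tune_svm <- function(map, markers, grid = svm_grid(), seed = 1) {
  profiles <- .profiles_of(map)
  tr <- .marker_training(profiles, markers)
  counts <- table(tr$y)
  if (any(counts[counts > 0] < 2))
    stop("compartment(s) with < 2 markers: ",
         paste(names(counts)[counts > 0 & counts < 2], collapse = ", "))
  pts <- expand.grid(cost = grid$cost, sigma = grid$sigma)
  with_seed(derive_seed(seed, "tune"), {
    # pre-draw the stratified splits, shared across grid points
    splits <- lapply(seq_len(grid$inner_reps), function(i) {
      unlist(lapply(levels(tr$y), function(l) {
        ix <- which(tr$y == l)
        if (!length(ix)) return(integer(0))
        n_tr <- max(1, round(grid$train_fraction * length(ix)))
        if (n_tr >= length(ix)) n_tr <- length(ix) - 1
        ix[sample.int(length(ix), n_tr)]
      }))
    })
    pts$macro_f1 <- vapply(seq_len(nrow(pts)), function(g) {
      mean(vapply(splits, function(trn) {
        fit <- .fit_svm(tr$x[trn, , drop = FALSE], droplevels(tr$y[trn]),
                        pts$cost[g], pts$sigma[g], probability = FALSE)
        pred <- predict(fit, tr$x[-trn, , drop = FALSE])
        macro_f1(.confusion(tr$y[-trn], as.character(pred),
                            levels(tr$y)))
      }, 1.0))
    }, 1.0)
    ord <- order(-pts$macro_f1, pts$cost, pts$sigma)
    best <- pts[ord[1], ]
    list(cost = best$cost, sigma = best$sigma,
         cv_macro_f1 = cv_macro_f1(profiles, markers, best$cost,
                                   best$sigma, folds = grid$outer_folds,
                                   seed = derive_seed(seed, "tune-cv")),
         grid_scores = pts)
  })
}

#' Stratified k-fold cross-validated macro F1 of marker self-prediction
#'
#' @inheritParams tune_svm
#' @param cost,sigma SVM hyperparameters.
#' @param folds number of folds.
#' @return mean macro F1 over folds.
#' @export
cv_macro_f1 <- function(map, markers, cost, sigma, folds = 5, seed = 1) {
  profiles <- .profiles_of(map)
  tr <- .marker_training(profiles, markers)
  with_seed(derive_seed(seed, "cv"), {
    fold <- integer(length(tr$y))
    for (l in levels(tr$y)) {
      ix <- which(tr$y == l)
      fold[ix] <- sample(rep_len(seq_len(folds), length(ix)))
    }
    mean(vapply(seq_len(folds), function(k) {
      trn <- which(fold != k)
      fit <- .fit_svm(tr$x[trn, , drop = FALSE], droplevels(tr$y[trn]),
                      cost, sigma, probability = FALSE)
      pred <- predict(fit, tr$x[-trn, , drop = FALSE])
      macro_f1(.confusion(tr$y[-trn], as.character(pred), levels(tr$y)))
    }, 1.0))
  })
}

# Wu-Lin pairwise coupling: turn a K x K matrix of pairwise
# probabilities r[i,j] = P(class i | i or j) into class probabilities.
.couple_pairwise <- function(r) {
  K <- nrow(r)
  if (K == 1) return(stats::setNames(1, rownames(r)))
  Q <- matrix(0, K, K, dimnames = dimnames(r))
  for (i in seq_len(K)) for (j in seq_len(K))
    Q[i, j] <- if (i == j) sum(r[-i, i]^2) else -r[j, i] * r[i, j]
  A <- rbind(cbind(Q, 1), c(rep(1, K), 0))
  sol <- tryCatch(solve(A, c(rep(0, K), 1)),
                  error = function(e) rep(1 / K, K + 1))
  p <- pmax(sol[seq_len(K)], 0)
  stats::setNames(p / sum(p), rownames(r))
}

#' Per-class SVM membership probabilities
#'
#' One-vs-one decision values are mapped through sigmoids with a fixed
#' slope (`score_slope`) per unit of the pair's typical training margin
#' (median absolute decision value of the pair's own markers), then
#' coupled into class probabilities (Wu-Lin). A profile deep inside a
#' marker cluster scores near 1; a profile on the boundary between two
#' clusters, or far from all of them, scores low.
#'
#' @param fit an `e1071::svm` fit on the marker profiles.
#' @param profiles proteins-by-fractions matrix to score.
#' @param train_x,train_y marker profiles and labels the fit was trained
#'   on (used to standardize the decision-value scale).
#' @param score_slope sigmoid steepness at the typical training margin.
#' @return proteins-by-classes probability matrix.
#' @export
svm_class_probabilities <- function(fit, profiles, train_x, train_y,
                                    score_slope = 5) {
  dv <- attr(predict(fit, profiles, decision.values = TRUE),
             "decision.values")
  dv <- dv[rownames(profiles), , drop = FALSE]
  dv_tr <- attr(predict(fit, train_x, decision.values = TRUE),
                "decision.values")
  cls <- levels(droplevels(train_y))
  pairs <- do.call(rbind, strsplit(colnames(dv), "/"))
  scale_k <- vapply(seq_len(nrow(pairs)), function(k)
    max(stats::median(abs(dv_tr[train_y %in% pairs[k, ], k])), 1e-6), 1.0)
  sig <- 1 / (1 + exp(-score_slope * sweep(dv, 2, scale_k, "/")))
  out <- matrix(NA_real_, nrow(profiles), length(cls),
                dimnames = list(rownames(profiles), cls))
  r <- matrix(0.5, length(cls), length(cls),
              dimnames = list(cls, cls))
  for (n in seq_len(nrow(profiles))) {
    for (k in seq_len(nrow(pairs))) {
      r[pairs[k, 1], pairs[k, 2]] <- sig[n, k]
      r[pairs[k, 2], pairs[k, 1]] <- 1 - sig[n, k]
    }
    out[n, ] <- .couple_pairwise(r)
  }
  out
}

#' Classify a map with a marker-trained SVM
#'
#' Trains a multiclass RBF SVM on all marker proteins and scores every
#' non-marker protein; the SVM score is the maximum per-class membership
#' probability (see [svm_class_probabilities()]), and non-marker
#' predictions scoring below `threshold` are labeled `"unknown"`. Marker
#' proteins retain their annotated compartment (their reported score is
#' the model's probability for that class).
#'
#' @inheritParams tune_svm
#' @param cost,sigma tuned hyperparameters.
#' @param threshold classification threshold on the SVM score.
#' @param score_slope see [svm_class_probabilities()].
#' @return a `classified_map`: list with `profiles` (matrix),
#'   `assignments` (data frame: accession, compartment, score, marker)
#'   and `taxonomy`.
#' @export
classify_map <- function(map, markers, cost, sigma, threshold = 0.7,
                         seed = 1, score_slope = 5) {
  profiles <- .profiles_of(map)
  tr <- .marker_training(profiles, markers)
  fit <- with_seed(derive_seed(seed, "classify"),
                   .fit_svm(tr$x, droplevels(tr$y), cost, sigma,
                            probability = FALSE))
  if (ncol(profiles) != ncol(tr$x))
    stop("fraction count differs between map and training profiles")
  prob <- svm_class_probabilities(fit, profiles, tr$x, droplevels(tr$y),
                                  score_slope = score_slope)
  best <- colnames(prob)[max.col(prob, ties.method = "first")]
  score <- prob[cbind(seq_len(nrow(prob)), match(best, colnames(prob)))]
  is_marker <- rownames(profiles) %in% tr$accession
  compartment <- ifelse(score >= threshold, best, "unknown")
  # markers keep their annotation; score = probability of that class
  mi <- match(rownames(profiles)[is_marker], tr$accession)
  compartment[is_marker] <- as.character(tr$y[mi])
  score[is_marker] <- prob[cbind(which(is_marker),
                                 match(as.character(tr$y[mi]),
                                       colnames(prob)))]
  structure(list(
    profiles = profiles,
    assignments = data.frame(accession = rownames(profiles),
                             compartment = compartment, score = score,
                             marker = is_marker, row.names = NULL,
                             stringsAsFactors = FALSE),
    taxonomy = markers$taxonomy
  ), class = "classified_map")
}

#' @export
print.classified_map <- function(x, ...) {
  a <- x$assignments
  cat(sprintf(paste0("classified_map: %d proteins (%d markers), ",
                     "%d classified, %d unknown\n"),
              nrow(a), sum(a$marker),
              sum(!a$marker & a$compartment != "unknown"),
              sum(a$compartment == "unknown")))
  invisible(x)
}

#' QSep map-resolution matrix
#'
#' Entry `(i, j)` is the mean pairwise euclidean distance between markers
#' of cluster i and cluster j, normalized to the mean within-cluster
#' pairwise distance of the reference cluster j; the diagonal is 1 by
#' construction. Larger off-diagonal entries indicate better resolved
#' clusters.
#'
#' @inheritParams tune_svm
#' @return class-by-class matrix of normalized distances.
#' @export
qsep <- function(map, markers) {
  profiles <- .profiles_of(map)
  tr <- .marker_training(profiles, markers)
  classes <- levels(droplevels(tr$y))
  idx <- lapply(classes, function(l) which(tr$y == l))
  names(idx) <- classes
  small <- classes[vapply(idx, length, 1L) < 2]
  if (length(small))
    stop("singleton marker cluster(s): ", paste(small, collapse = ", "))
  D <- as.matrix(stats::dist(tr$x))
  mean_between <- function(i, j) {
    if (identical(i, j)) {
      d <- D[i, j, drop = FALSE]
      mean(d[upper.tri(d)])
    } else mean(D[i, j, drop = FALSE])
  }
  within <- vapply(idx, function(i) mean_between(i, i), 1.0)
  out <- matrix(1, length(classes), length(classes),
                dimnames = list(classes, classes))
  for (a in seq_along(classes)) for (b in seq_along(classes))
    out[a, b] <- mean_between(idx[[a]], idx[[b]]) / within[b]
  out
}
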