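metric_columns <- c("OBS", "SW", "VIS", "ABS", "AS", "MS", "HOM", "GS",
                    "TS", "CS")

#' Nonparametric group comparison with Holm-Bonferroni correction
#'
#' Compares two labelled groups of activation summaries metric by metric with
#' the Mann-Whitney rank-sum test (or the Wilcoxon signed-rank test when rows
#' are paired by subject), then adjusts the p-values over the metric family
#' with Holm's step-down procedure.
#'
#' @param data data.frame of activation summaries: one row per activation,
#'   metric columns plus a `condition` column (exactly two levels used) and
#'   optionally `subject_id`.
#' @param metrics character vector of metric columns to test (default: the ten
#'   node metrics present in `data`).
#' @param conditions length-2 character vector picking and ordering the two
#'   conditions (default: the two levels found).
#' @param paired if TRUE, rows are matched by `subject_id` across conditions
#'   and a signed-rank test is used.
#' @param alpha family-wise significance level for the `significant` flag.
#' @return data.frame: metric, statistic, p, p_holm, significant.
#' @export
compare_groups <- function(data, metrics = NULL, conditions = NULL,
                           paired = FALSE, alpha = 0.05) {
  if (is.null(metrics))
    metrics <- intersect(metric_columns, names(data))
  if (!length(metrics)) stop("no metric columns found", call. = FALSE)
  if (is.null(conditions)) conditions <- unique(as.character(data$condition))
  if (length(conditions) != 2L)
    stop("exactly two conditions required", call. = FALSE)
  a <- data[data$condition == conditions[1L], , drop = FALSE]
  b <- data[data$condition == conditions[2L], , drop = FALSE]
  if (nrow(a) < 2L || nrow(b) < 2L)
    stop("each condition needs at least 2 rows", call. = FALSE)
  if (paired) {
    ids <- intersect(a$subject_id, b$subject_id)
    a <- a[match(ids, a$subject_id), , drop = FALSE]
    b <- b[match(ids, b$subject_id), , drop = FALSE]
  }
  res <- lapply(metrics, function(m) {
    tst <- suppressWarnings(stats::wilcox.test(a[[m]], b[[m]],
                                               paired = paired,
                                               exact = FALSE))
    data.frame(metric = m, statistic = unname(tst$statistic),
               p = tst$p.value)
  })
  res <- do.call(rbind, res)
  res$p_holm <- stats::p.adjust(res$p, method = "holm")
  res$significant <- res$p_holm < alpha
  res
}

#' Random-forest dose classifier with leave-one-out validation
#'
#' Trains a random forest on per-activation summary metrics to predict the
#' condition label (e.g. NMDA-blockade dose category) and evaluates it by
#' leave-one-out cross-validation at the activation (row) level. Features are
#' standardized with the training fold's means and standard deviations.
#'
#' @param data data.frame: metric columns plus `condition` (the class label)
#'   and optionally `subject_id`.
#' @param n_trees trees per forest (default 50).
#' @param seed integer seed; results are reproducible given the seed.
#' @param metrics feature columns (default: the ten node metrics present).
#' @param by_subject if TRUE, hold out all rows of a subject together instead
#'   of single rows.
#' @return List with `model` (a forest trained on all rows), `confusion`
#'   (true x predicted counts from leave-one-out), `accuracy`, `n_trees`,
#'   `validation`, and the standardization (`center`, `scale`) of the full
#'   model.
#' @export
dose_classifier <- function(data, n_trees = 50, seed = 1, metrics = NULL,
                            by_subject = FALSE) {
  if (is.null(metrics))
    metrics <- intersect(metric_columns, names(data))
  y <- factor(data$condition)
  if (nlevels(y) < 2L) stop("need at least 2 conditions", call. = FALSE)
  cnt <- table(y)
  if (any(cnt < 2L))
    warning("condition(s) with a single row can never be predicted as ",
            "their own class under leave-one-out: ",
            paste(names(cnt)[cnt < 2L], collapse = ", "))
  x <- as.matrix(data[, metrics, drop = FALSE])
  x[is.na(x)] <- 0
  folds <- if (by_subject) split(seq_len(nrow(x)), data$subject_id)
           else as.list(seq_len(nrow(x)))
  pred <- factor(rep(NA_character_, nrow(x)), levels = levels(y))
  for (k in seq_along(folds)) {
    hold <- folds[[k]]
    tr <- setdiff(seq_len(nrow(x)), hold)
    ctr <- colMeans(x[tr, , drop = FALSE])
    scl <- apply(x[tr, , drop = FALSE], 2, stats::sd)
    scl[scl == 0] <- 1
    xtr <- scale(x[tr, , drop = FALSE], ctr, scl)
    xte <- scale(x[hold, , drop = FALSE], ctr, scl)
    set.seed(seed + k)
    fit <- randomForest::randomForest(xtr, droplevels(y[tr]),
                                      ntree = n_trees)
    pred[hold] <- as.character(stats::predict(fit, xte))
  }
  confusion <- table(true = y, predicted = pred)
  acc <- sum(diag(confusion)) / sum(confusion)
  ctr <- colMeans(x); scl <- apply(x, 2, stats::sd); scl[scl == 0] <- 1
  set.seed(seed)
  full <- randomForest::randomForest(scale(x, ctr, scl), y, ntree = n_trees)
  list(model = full, center = ctr, scale = scl, metrics = metrics,
       confusion = confusion, accuracy = acc, n_trees = n_trees,
       validation = if (by_subject) "leave-one-subject-out"
                    else "leave-one-out")
}

#' Apply a trained classifier to new data and score category consistency
#'
#' Predicts a category for every row and counts, per true condition, how many
#' predictions fall into the category set declared consistent for that
#' condition (e.g. young -> baseline; aged -> any blockade dose).
#'
#' @param classifier result of [dose_classifier()].
#' @param data data.frame with the classifier's feature columns and a
#'   `condition` column.
#' @param mapping named list: for each condition, the character vector of
#'   predicted categories counted as consistent.
#' @return List with `predicted` (factor), `per_condition` (data.frame:
#'   condition, n, n_consistent) and `fraction_consistent` overall.
#' @export
transfer_classify <- function(classifier, data, mapping) {
  conds <- unique(as.character(data$condition))
  missing_ <- setdiff(conds, names(mapping))
  if (length(missing_))
    stop("no mapping for condition(s): ", paste(missing_, collapse = ", "),
         call. = FALSE)
  x <- as.matrix(data[, classifier$metrics, drop = FALSE])
  x[is.na(x)] <- 0
  xs <- scale(x, classifier$center, classifier$scale)
  pred <- stats::predict(classifier$model, xs)
  per <- lapply(conds, function(cc) {
    sel <- data$condition == cc
    data.frame(condition = cc, n = sum(sel),
               n_consistent = sum(as.character(pred[sel]) %in%
                                    mapping[[cc]]))
  })
  per <- do.call(rbind, per)
  list(predicted = pred, per_condition = per,
       fraction_consistent = sum(per$n_consistent) / sum(per$n))
}

#' Fraction of predictions consistent with declared category sets
#'
#' Bookkeeping helper: given per-condition counts of consistent predictions,
#' returns the overall consistent fraction (e.g. 30/40 young + 22/30 aged
#' gives 52/70 = 74\%).
#'
#' @param n_consistent,n integer vectors, one entry per condition.
#' @return Overall fraction in [0, 1].
#' @export
consistency_fraction <- function(n_consistent, n) {
  if (any(n_consistent > n) || any(n < 0))
    stop("counts out of range", call. = FALSE)
  sum(n_consistent) / sum(n)
}

#' Randomly drop edges to a target mean degree
#'
#' Removes supra-threshold edges uniformly at random, pooled across all
#' snapshots and without replacement, until the network's mean degree per
#' observed node first reaches the target. Mimics a loss of functional
#' connections while leaving node identity untouched: nodes that lose all
#' edges drop out of their snapshots' node sets (an unconnected pixel is no
#' longer observed), so the mean degree is evaluated against the original
#' node observations.
#'
#' @param net a `temporal_network`.
#' @param target_mean_degree desired mean degree (2 x edges / node
#'   observations, computed on the original node sets); must not exceed the
#'   current mean degree.
#' @param seed integer seed.
#' @return A `temporal_network` with fewer edges.
#' @export
drop_edges <- function(net, target_mean_degree, seed = 1) {
  stopifnot(inherits(net, "temporal_network"))
  ne <- vapply(net$snapshots, function(s) nrow(s$edges), integer(1))
  n_obs <- sum(vapply(net$snapshots, function(s) length(s$nodes), integer(1)))
  if (n_obs == 0L) return(net)
  cur <- 2 * sum(ne) / n_obs
  if (target_mean_degree > cur + 1e-12)
    stop("target mean degree exceeds the current mean degree", call. = FALSE)
  n_keep <- floor(target_mean_degree * n_obs / 2)
  total <- sum(ne)
  set.seed(seed)
  keep_flat <- sort(sample.int(total, n_keep))
  offs <- cumsum(c(0L, ne))
  snaps <- net$snapshots
  for (k in seq_along(snaps)) {
    local_ <- keep_flat[keep_flat > offs[k] & keep_flat <= offs[k + 1L]] -
      offs[k]
    ed <- snaps[[k]]$edges[local_, , drop = FALSE]
    rownames(ed) <- NULL
    snaps[[k]]$edges <- ed
    snaps[[k]]$nodes <- sort(unique(c(ed$i, ed$j)))
  }
  out <- net
  out$snapshots <- snaps
  out
}
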