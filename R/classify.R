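#' Build the antecedent-query feature matrix
#'
#' Represents each user by the number of times they queried for each
#' symptom and each condition strictly before their index date: for target
#' users that is their first CRQ (`t0`); comparison users, who have no CRQ,
#' are anchored at a pseudo-index date drawn uniformly (with `seed`) from
#' the target users' `t0` distribution so both classes are censored the
#' same way. Columns are one count per symptom concept then one per
#' condition concept, each block in lexicographic concept order; rows keep
#' input order (targets first). Users with no queries before their index
#' date keep an all-zero row.
#'
#' @param targets `data.table` with columns `user_id` and `t0` (e.g. cohort
#'   members, optionally filtered to one interest class).
#' @param comparison_users Character vector of comparison user ids.
#' @param records Records `data.table` covering all these users.
#' @param symptom_lexicon,condition_lexicon `lexicon` objects.
#' @param seed Integer seed for the pseudo-index draw.
#' @return A list of class `feature_matrix`: `X` (integer matrix, users x
#'   concepts), `y` (1 = target, 0 = comparison), `user_id`, `t0`.
#' @export
build_feature_matrix <- function(targets, comparison_users, records,
                                 symptom_lexicon, condition_lexicon,
                                 seed = 1L) {
  if (inherits(targets, "cohort")) targets <- targets$members
  targets <- as.data.table(targets)[, .(user_id, t0)]
  if (!nrow(targets)) stop("no target users")
  pseudo <- with_seed(seed, targets$t0[
    sample.int(nrow(targets), length(comparison_users), replace = TRUE)])
  users <- rbind(
    targets[, .(user_id, t0, label = 1L)],
    data.table(user_id = as.character(comparison_users), t0 = pseudo,
               label = 0L)
  )
  if (anyDuplicated(users$user_id)) {
    stop("target and comparison user sets overlap")
  }

  cols <- c(paste0("symptom.", sort(lexicon_concepts(symptom_lexicon))),
            paste0("condition.", sort(lexicon_concepts(condition_lexicon))))
  X <- matrix(0L, nrow = nrow(users), ncol = length(cols),
              dimnames = list(users$user_id, cols))

  pre <- records[users, on = "user_id", nomatch = 0L][timestamp < t0]
  for (lex in list(symptom_lexicon, condition_lexicon)) {
    if (!nrow(pre)) break
    mm <- match_concepts_bulk(pre$norm_text, lex)
    if (!nrow(mm)) next
    cnt <- data.table(user_id = pre$user_id[mm$.idx],
                      col = paste0(lex$category, ".", mm$concept_id))[
      , .(n = .N), by = .(user_id, col)]
    X[cbind(match(cnt$user_id, users$user_id), match(cnt$col, cols))] <-
      cnt$n
  }
  structure(list(X = X, y = users$label, user_id = users$user_id,
                 t0 = users$t0),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d users (%d target, %d comparison) x %d concepts\n",
              nrow(x$X), sum(x$y == 1L), sum(x$y == 0L), ncol(x$X)))
  invisible(x)
}

#' Cross-validated AUC of an antecedent-query classifier
#'
#' Evaluates how well antecedent symptom/condition query counts
#' discriminate the target class from the comparison class, with stratified
#' k-fold cross-validation and the area under the ROC curve on held-out
#' scores. Two model specifications are supported: `"linear_regression"`
#' fits ordinary least squares to the 0/1 label and ranks its continuous
#' fitted score (deliberately not logistic regression), and
#' `"random_forest"` fits a classification forest (default 50 trees) and
#' ranks the out-of-fold class-1 probability. Folds are assigned
#' stratified within class on users sorted by id under `seed`, so results
#' are deterministic given inputs and seed. AUC is rank-based and therefore
#' invariant to any strictly monotone transform of the scores.
#'
#' @param fm A `feature_matrix` from [build_feature_matrix()].
#' @param model `"linear_regression"` or `"random_forest"`.
#' @param n_trees Trees for the random forest.
#' @param folds Number of cross-validation folds.
#' @param seed Integer seed (fold assignment and forest growth).
#' @return A list of class `auc_result`: `mean_auc`, `fold_auc`, `model`,
#'   `folds`.
#' @export
evaluate_auc <- function(fm, model = c("linear_regression",
                                       "random_forest"),
                         n_trees = 50L, folds = 10L, seed = 1L) {
  model <- match.arg(model)
  stopifnot(inherits(fm, "feature_matrix"), folds >= 2L)
  y <- fm$y
  if (length(unique(y)) < 2L) {
    stop("both classes must be present to evaluate discrimination")
  }

  with_seed(seed, {
    # stratified fold assignment on users sorted by id
    fold <- integer(length(y))
    ord <- order(fm$user_id)
    for (cl in c(0L, 1L)) {
      rows <- ord[y[ord] == cl]
      fold[rows] <- sample(rep_len(seq_len(folds), length(rows)))
    }
    fold_auc <- vapply(seq_len(folds), function(k) {
      tr <- fold != k
      te <- !tr
      scores <- fit_score(fm$X[tr, , drop = FALSE], y[tr],
                          fm$X[te, , drop = FALSE], model, n_trees)
      as.numeric(pROC::auc(pROC::roc(response = y[te],
                                     predictor = scores,
                                     levels = c(0L, 1L), direction = "<",
                                     quiet = TRUE)))
    }, numeric(1L))
    structure(list(mean_auc = mean(fold_auc), fold_auc = fold_auc,
                   model = model, folds = folds),
              class = "auc_result")
  })
}

fit_score <- function(Xtr, ytr, Xte, model, n_trees) {
  if (length(unique(ytr)) < 2L) {
    stop("a training fold lost one class; use stratified folds")
  }
  if (model == "linear_regression") {
    fit <- lm.fit(cbind(1, Xtr), ytr)
    b <- fit$coefficients
    b[is.na(b)] <- 0  # rank-deficient (constant) columns contribute nothing
    drop(cbind(1, Xte) %*% b)
  } else {
    rf <- randomForest::randomForest(x = Xtr, y = factor(ytr,
                                                         levels = c(0L, 1L)),
                                     ntree = n_trees)
    predict(rf, Xte, type = "prob")[, "1"]
  }
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("<auc_result> %s, %d-fold CV: mean AUC = %.3f (folds %s)\n",
              x$model, x$folds, x$mean_auc,
              paste(sprintf("%.2f", x$fold_auc), collapse = " ")))
  invisible(x)
}
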