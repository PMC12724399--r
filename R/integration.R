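# Four-assay integration: the assay matrix, dominant-negative calls,
# PCA/k-means mechanism clustering, and classifier combination.

# DN cutoffs per assay: a variant counts as "reduced" in an assay when its
# score is strictly below the cutoff. The heterozygous function cutoff is 0,
# not 0.25: only scores below the haploinsufficient (nonsense) level implicate
# the wild-type allele.
DN_CUTOFFS <- c(abundance = 0.25, "function" = 0.25,
                het_abundance = 0.25, het_function = 0)

#' Assemble the four-assay score matrix
#'
#' Outer join of the four score sets on variant identity. The `complete` flag
#' marks variants measured in all four assays.
#'
#' @param score_sets Named list of four `score_set`s with names `abundance`,
#'   `function`, `het_abundance`, `het_function` (or a list whose `assay`
#'   attributes identify them).
#' @return `data.frame` of class `assay_matrix`: identity columns, one score
#'   column per assay, `complete`.
#' @export
assemble_matrix <- function(score_sets) {
  if (is.null(names(score_sets)) || !all(nzchar(names(score_sets)))) {
    names(score_sets) <- vapply(score_sets, function(s) attr(s, "assay"), "")
  }
  if (!setequal(names(score_sets), ASSAYS)) {
    stop2("need exactly one score set per assay: ", paste(ASSAYS, collapse = ", "))
  }
  for (a in ASSAYS) {
    if (anyDuplicated(score_sets[[a]]$variant_id)) {
      stop2("duplicate variant within the ", a, " score set")
    }
  }
  ids <- sort(unique(unlist(lapply(score_sets, `[[`, "variant_id"))))
  out <- data.frame(variant_id = ids, stringsAsFactors = FALSE)
  id_cols <- c("position", "wt", "alt", "consequence")
  out[id_cols] <- NA
  for (a in ASSAYS) {
    s <- score_sets[[a]]
    m <- match(ids, s$variant_id)
    out[[a]] <- s$score[m]
    fill <- is.na(out$position) & !is.na(m)
    out[fill, id_cols] <- s[m[fill], id_cols]
  }
  out$complete <- !is.na(out$abundance) & !is.na(out[["function"]]) &
    !is.na(out$het_abundance) & !is.na(out$het_function)
  class(out) <- c("assay_matrix", "data.frame")
  out
}

#' Call dominant-negative variants from the four assays
#'
#' Counts, for each complete missense variant, the assays in which its score
#' falls strictly below the assay's cutoff (0.25, 0.25, 0.25 and 0 for
#' abundance, function, heterozygous abundance and heterozygous function).
#' Reduced function in all four assays is a severe dominant negative; in
#' three of four, a strong dominant negative.
#'
#' @param mat An `assay_matrix`.
#' @param cutoffs Named cutoff vector (defaults as above).
#' @return `data.frame` with `variant_id`, `n_assays_below_cutoff`, `label`
#'   (`severe_dn`, `strong_dn`, `none`) and `missing_data` flag for
#'   incomplete rows.
#' @export
call_dominant_negative <- function(mat, cutoffs = DN_CUTOFFS) {
  stopifnot(setequal(names(cutoffs), ASSAYS))
  miss <- mat$consequence == "missense"
  below <- vapply(ASSAYS, function(a) as.integer(mat[[a]] < cutoffs[[a]]),
                  integer(nrow(mat)))
  if (!is.matrix(below)) below <- matrix(below, nrow = nrow(mat))
  n_below <- rowSums(below)
  label <- rep("none", nrow(mat))
  ok <- mat$complete & miss & !is.na(n_below)
  label[ok & n_below == 4] <- "severe_dn"
  label[ok & n_below == 3] <- "strong_dn"
  data.frame(
    variant_id = mat$variant_id,
    n_assays_below_cutoff = ifelse(mat$complete, n_below, NA_integer_),
    label = label,
    missing_data = !mat$complete,
    stringsAsFactors = FALSE
  )
}

#' PCA and k-means clustering of the four-assay matrix
#'
#' Standardizes the four scores over complete variants (zero mean, unit
#' variance per assay), projects with PCA (all four components retained), and
#' clusters the standardized matrix with k-means (k-means++-style robustness
#' via many restarts under a fixed seed). Clusters are auto-named from their
#' centroid profiles on the original score scale: all four low = dominant
#' negative; variant-only assays low with normal wild-type-allele abundance =
#' haploinsufficient; function above the normal range = gain-of-function;
#' function between 0.25 and the normal range = partial loss-of-function;
#' everything near 1 = normal (two normal clusters are numbered by size).
#'
#' @param mat An `assay_matrix`.
#' @param k Number of clusters.
#' @param seed RNG seed for the k-means restarts.
#' @param n_init Number of random restarts.
#' @param normal_bounds Synonymous normal range used by the naming rules.
#' @return List of class `mave_clusters`: `assignments` (variant_id, cluster
#'   index, cluster name, PC1, PC2), `centers` (original-scale centroids),
#'   `pca` (the `prcomp` fit), `names` (cluster index -> name).
#' @export
pca_kmeans <- function(mat, k = 6L, seed = 1L, n_init = 50L,
                       normal_bounds = c(0.75, 1.25)) {
  if (k < 2) stop2("k must be at least 2")
  cm <- mat[mat$complete, , drop = FALSE]
  x <- as.matrix(cm[, ASSAYS])
  xs <- scale(x)
  pca <- stats::prcomp(xs, center = FALSE, scale. = FALSE)
  km <- with_seed(seed, stats::kmeans(xs, centers = k, nstart = n_init,
                                      iter.max = 100))
  centers_orig <- km$centers * matrix(attr(xs, "scaled:scale"), k, 4, byrow = TRUE) +
    matrix(attr(xs, "scaled:center"), k, 4, byrow = TRUE)
  colnames(centers_orig) <- ASSAYS
  nm <- name_clusters(centers_orig, km$size, normal_bounds)
  assignments <- data.frame(
    variant_id = cm$variant_id,
    cluster = km$cluster,
    cluster_name = nm[km$cluster],
    PC1 = pca$x[, 1],
    PC2 = pca$x[, 2],
    stringsAsFactors = FALSE
  )
  structure(list(assignments = assignments, centers = centers_orig,
                 pca = pca, names = nm, kmeans = km),
            class = "mave_clusters")
}

# Pure function of centroids (original score scale) and cluster sizes.
name_clusters <- function(centers, sizes, normal_bounds) {
  low <- 0.25
  nm <- character(nrow(centers))
  for (i in seq_len(nrow(centers))) {
    ab <- centers[i, "abundance"]; fn <- centers[i, "function"]
    ha <- centers[i, "het_abundance"]; hf <- centers[i, "het_function"]
    nm[i] <- if (ab < low && fn < low && ha < low && hf < low) {
      "dominant negative"
    } else if (ab < low && fn < low) {
      "haploinsufficient"
    } else if (fn > normal_bounds[2]) {
      "gain-of-function"
    } else if (fn < normal_bounds[1]) {
      "partial loss-of-function"
    } else {
      "normal"
    }
  }
  # Number duplicate names by decreasing cluster size (normal 1, normal 2, ...)
  for (base in unique(nm[duplicated(nm)])) {
    idx <- which(nm == base)
    idx <- idx[order(-sizes[idx])]
    nm[idx] <- paste(base, seq_along(idx))
  }
  nm
}

#' @export
print.mave_clusters <- function(x, ...) {
  cat("<mave_clusters> k =", nrow(x$centers), "\n")
  tab <- table(x$assignments$cluster_name)
  print(tab)
  invisible(x)
}

#' Combine the four assays into a single classifier score
#'
#' Trains logistic regression, random forest and Gaussian naive Bayes on
#' labeled complete missense variants, evaluates each by leave-one-out
#' cross-validation (positive class: pathogenic), and refits on all labels to
#' score unlabeled variants. Logistic regression and naive Bayes use
#' standardized scores; the random forest uses raw scores (scale-invariant).
#'
#' @param mat An `assay_matrix`.
#' @param truth `data.frame` with `variant_id` and `label`
#'   (`"P_LP"`/`"B_LB"`).
#' @param seed RNG seed (random forest).
#' @param min_labeled Minimum labeled variants required.
#' @return List of class `mave_classifiers`: `loo` (per labeled variant LOO
#'   probabilities per model), `auc` (named AUC vector), `predictions`
#'   (positive-class probability for unlabeled complete missense variants,
#'   per model and for the best model).
#' @export
combine_classifiers <- function(mat, truth, seed = 1L, min_labeled = 20L) {
  cm <- mat[mat$complete & mat$consequence == "missense", , drop = FALSE]
  lab <- truth$label[match(cm$variant_id, truth$variant_id)]
  labeled <- which(!is.na(lab))
  if (length(unique(lab[labeled])) < 2) stop2("truth set has a single class")
  if (length(labeled) < min_labeled) {
    stop2("need at least ", min_labeled, " labeled complete missense variants")
  }
  x <- as.matrix(cm[, ASSAYS])
  colnames(x) <- c("abundance", "fn", "het_abundance", "het_fn")
  xs <- scale(x)
  y <- factor(ifelse(lab == "P_LP", "pathogenic", "benign"),
              levels = c("benign", "pathogenic"))

  fit_predict <- function(train, test) {
    dtr_s <- data.frame(xs[train, , drop = FALSE], y = y[train])
    dte_s <- data.frame(xs[test, , drop = FALSE])
    dtr_r <- data.frame(x[train, , drop = FALSE], y = y[train])
    dte_r <- data.frame(x[test, , drop = FALSE])
    lr <- suppressWarnings(stats::glm(y ~ ., data = dtr_s, family = stats::binomial()))
    p_lr <- suppressWarnings(stats::predict(lr, dte_s, type = "response"))
    rf <- with_seed(seed, randomForest::randomForest(y ~ ., data = dtr_r))
    p_rf <- stats::predict(rf, dte_r, type = "prob")[, "pathogenic"]
    nb <- e1071::naiveBayes(y ~ ., data = dtr_s)
    p_nb <- stats::predict(nb, dte_s, type = "raw")[, "pathogenic"]
    cbind(lr = p_lr, rf = p_rf, gnb = p_nb)
  }

  loo <- matrix(NA_real_, length(labeled), 3,
                dimnames = list(NULL, c("lr", "rf", "gnb")))
  for (i in seq_along(labeled)) {
    tr <- labeled[-i]
    loo[i, ] <- fit_predict(tr, labeled[i])
  }
  auc <- apply(loo, 2, function(p) {
    classifier_auc(p, y[labeled] == "pathogenic")
  })

  unlabeled <- which(is.na(lab))
  preds <- NULL
  if (length(unlabeled)) {
    pm <- fit_predict(labeled, unlabeled)
    preds <- data.frame(variant_id = cm$variant_id[unlabeled], pm,
                        stringsAsFactors = FALSE)
    preds$best <- pm[, names(which.max(auc))]
  }
  structure(list(
    loo = data.frame(variant_id = cm$variant_id[labeled],
                     label = as.character(y[labeled]), loo,
                     stringsAsFactors = FALSE),
    auc = auc,
    best_model = names(which.max(auc)),
    predictions = preds
  ), class = "mave_classifiers")
}

# AUC where higher probability means positive class (rank / Mann-Whitney).
classifier_auc <- function(p, positive) {
  r <- rank(p)
  n1 <- sum(positive); n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
print.mave_classifiers <- function(x, ...) {
  cat("<mave_classifiers> leave-one-out AUC:\n")
  print(round(x$auc, 3))
  cat("best model:", x$best_model, "\n")
  invisible(x)
}
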