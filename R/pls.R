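# mc_task_pls module: mean-centered Task Partial Least Squares with
# permutation and bootstrap inference.

#' Construct a PLS data block
#'
#' Rows are (subject, condition) observations, columns are metric elements
#' (e.g. a flattened timescale x frequency grid). Missing elements stay `NA`
#' and are excluded pairwise from cell means.
#'
#' @param x numeric matrix, rows = observations.
#' @param subject,group,condition label vectors, one entry per row.
#' @param elements optional element labels (default column names).
#' @return a `data_block`.
#' @export
data_block <- function(x, subject, group, condition, elements = colnames(x)) {
  x <- as.matrix(x)
  stopifnot(length(subject) == nrow(x), length(group) == nrow(x),
            length(condition) == nrow(x))
  if (anyDuplicated(paste(subject, condition, sep = "\r")))
    stop_param("duplicate (subject, condition) rows in data block")
  if (is.null(elements)) elements <- paste0("e", seq_len(ncol(x)))
  colnames(x) <- elements
  structure(list(x = x, subject = as.character(subject),
                 group = as.character(group),
                 condition = as.character(condition),
                 elements = as.character(elements)),
            class = "data_block")
}

#' Build a data block from a tidy metric table
#'
#' @param df data.frame with columns `subject`, `group`, `condition`,
#'   `element`, `value`; replicate rows (e.g. per segment) are averaged.
#' @return a `data_block`.
#' @export
data_block_from_tidy <- function(df) {
  need <- c("subject", "group", "condition", "element", "value")
  stopifnot(all(need %in% names(df)))
  agg <- aggregate(value ~ subject + group + condition + element, data = df,
                   FUN = mean, na.rm = TRUE, na.action = NULL)
  keys <- unique(agg[, c("subject", "group", "condition")])
  elements <- unique(agg$element)
  x <- matrix(NA_real_, nrow(keys), length(elements),
              dimnames = list(NULL, elements))
  idx_row <- match(paste(agg$subject, agg$condition),
                   paste(keys$subject, keys$condition))
  idx_col <- match(agg$element, elements)
  x[cbind(idx_row, idx_col)] <- agg$value
  data_block(x, keys$subject, keys$group, keys$condition, elements)
}

cell_index <- function(block, design) {
  cells <- design_cells(design)
  idx <- lapply(seq_len(nrow(cells)), function(c)
    which(block$group == cells$group[c] & block$condition == cells$condition[c]))
  empty <- vapply(idx, length, 0L) == 0L
  if (any(empty))
    stop_param("empty design cell(s): ",
               paste(paste(cells$group[empty], cells$condition[empty], sep = "/"),
                     collapse = ", "))
  list(cells = cells, idx = idx)
}

#' Group x condition cell-mean matrix, grand-mean centered
#'
#' One row per (group, condition) cell: the mean over that cell's subjects
#' of their metric rows, with the grand mean (mean over all cells) removed
#' column-wise. Missing elements are excluded from means element-wise.
#'
#' @param block a [data_block()].
#' @param design a [study_design()].
#' @return list with `M` (centered cells x elements), `cell_means`,
#'   `grand_mean`, `cells` (data.frame of cell labels).
#' @export
condition_mean_matrix <- function(block, design) {
  ci <- cell_index(block, design)
  cm <- do.call(rbind, lapply(ci$idx, function(i)
    colMeans(block$x[i, , drop = FALSE], na.rm = TRUE)))
  cm[is.nan(cm)] <- NA_real_
  grand <- colMeans(cm, na.rm = TRUE)
  M <- sweep(cm, 2L, grand)
  rownames(M) <- paste(ci$cells$group, ci$cells$condition, sep = "/")
  list(M = M, cell_means = cm, grand_mean = grand, cells = ci$cells)
}

#' SVD of the centered cell-mean matrix
#'
#' Decomposes `M = U diag(S) V'` truncated to `cells - 1` latent variables
#' (the rank bound after grand-mean centering). Sign convention: the
#' largest-magnitude element of each brain-salience column is positive.
#' Covariance explained by LV `l` is `S_l^2 / sum(S^2)`.
#'
#' @param M centered cells x elements matrix (`NA`-free).
#' @return list with `u` (task saliences), `s` (singular values), `v` (brain
#'   saliences), `cov_explained`.
#' @export
pls_svd <- function(M) {
  if (anyNA(M)) stop_param("cell-mean matrix contains missing elements; drop or impute upstream")
  if (all(M == 0)) stop("all-zero centered matrix: no effects to decompose")
  n_lv <- min(nrow(M) - 1L, ncol(M))
  dec <- svd(M, nu = n_lv, nv = n_lv)
  s <- dec$d[seq_len(n_lv)]
  u <- dec$u; v <- dec$v
  for (l in seq_len(n_lv)) {
    peak <- which.max(abs(v[, l]))
    if (v[peak, l] < 0) { v[, l] <- -v[, l]; u[, l] <- -u[, l] }
  }
  rownames(u) <- rownames(M); rownames(v) <- colnames(M)
  list(u = u, s = s, v = v, cov_explained = s^2 / sum(dec$d^2))
}

#' Brain scores: projection of observation rows onto brain saliences
#'
#' The score of a (subject, condition) row for LV `l` is the inner product of
#' its grand-mean-centered metric row with brain salience `v_l`. The
#' normalized display variant averages scores per design cell, mean-centers
#' across cells and divides by the singular value.
#'
#' @param block a [data_block()].
#' @param model a fitted `pls_model` (or the output of [pls_svd()] plus
#'   `grand_mean` and `cells`).
#' @return list with `scores` (rows x LV), `cell_scores` (cells x LV) and
#'   `cell_scores_norm`.
#' @export
brain_scores <- function(block, model) {
  if (!identical(colnames(block$x), model$elements))
    stop_param("element set of block does not match the fitted model")
  xc <- sweep(block$x, 2L, model$grand_mean)
  xc[is.na(xc)] <- 0                      # missing elements contribute zero
  scores <- xc %*% model$v
  key <- paste(block$group, block$condition, sep = "/")
  cells <- paste(model$cells$group, model$cells$condition, sep = "/")
  cell_scores <- t(vapply(cells, function(k)
    colMeans(scores[key == k, , drop = FALSE]), numeric(ncol(scores))))
  norm <- sweep(sweep(cell_scores, 2L, colMeans(cell_scores)), 2L, model$s, "/")
  list(scores = scores, cell_scores = cell_scores, cell_scores_norm = norm)
}

#' Permutation test on the singular values
#'
#' Observation rows are reassigned to (group, condition) cells without
#' replacement (unrestricted exchangeability; `scheme = "within_subject"`
#' instead shuffles condition labels within each subject, preserving group
#' membership). `p_l = (#\{S_perm >= S_obs\} + 1) / (n_perm + 1)`.
#'
#' @param block a [data_block()].
#' @param design a [study_design()].
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @param scheme exchangeability scheme.
#' @return numeric vector of p-values, one per latent variable.
#' @export
permutation_test <- function(block, design, n_perm = 1000, seed = 1L,
                             scheme = c("unrestricted", "within_subject")) {
  scheme <- match.arg(scheme)
  if (n_perm < 100) stop_param("n_perm must be >= 100")
  obs <- pls_svd(condition_mean_matrix(block, design)$M)
  set.seed(as.integer(seed))
  exceed <- numeric(length(obs$s))
  bp <- block
  for (p in seq_len(n_perm)) {
    if (scheme == "unrestricted") {
      ord <- sample(nrow(block$x))
      bp$x <- block$x[ord, , drop = FALSE]
    } else {
      ord <- seq_len(nrow(block$x))
      for (s in unique(block$subject)) {
        rows <- which(block$subject == s)
        ord[rows] <- rows[sample(length(rows))]
      }
      bp$x <- block$x[ord, , drop = FALSE]
    }
    sp <- svd(condition_mean_matrix(bp, design)$M)$d[seq_along(obs$s)]
    exceed <- exceed + (sp >= obs$s)
  }
  (exceed + 1) / (n_perm + 1)
}

procrustes_rotation <- function(ref, x) {
  dec <- svd(crossprod(x, ref))
  dec$u %*% t(dec$v)
}

#' Bootstrap test: element reliability and score confidence intervals
#'
#' Subjects are resampled with replacement within each group x condition
#' cell. Each replicate's saliences are aligned to the observed solution by
#' Procrustes rotation (SVD axes are sign/rotation unstable across
#' resamples). The bootstrap ratio of an element is its observed scaled
#' salience (`v * s`) divided by the SD of the aligned replicate values;
#' `|ratio| > 2.5758` approximates the 99th two-tailed percentile. 95%
#' percentile CIs are returned for the normalized cell-mean brain scores.
#'
#' @inheritParams permutation_test
#' @param n_boot number of bootstrap replicates (>= 100).
#' @return list with `ratios` (elements x LV), `score_ci_lo` / `score_ci_hi`
#'   (cells x LV), `score_reps` (the full cells x LV x replicate array, for
#'   derived intervals such as group-level ones), `cells`, `n_dropped`.
#' @export
bootstrap_test <- function(block, design, n_boot = 500, seed = 1L) {
  if (n_boot < 100) stop_param("n_boot must be >= 100")
  ci <- cell_index(block, design)
  if (any(vapply(ci$idx, length, 0L) < 3L))
    stop_param("each design cell needs >= 3 subjects for the bootstrap")
  cm <- condition_mean_matrix(block, design)
  obs <- pls_svd(cm$M)
  n_lv <- length(obs$s)
  set.seed(as.integer(seed))
  vs <- array(NA_real_, dim = c(nrow(obs$v), n_lv, n_boot))
  sc <- array(NA_real_, dim = c(nrow(cm$M), n_lv, n_boot))
  dropped <- 0L
  bb <- block
  for (b in seq_len(n_boot)) {
    take <- unlist(lapply(ci$idx, function(i) i[sample.int(length(i), replace = TRUE)]))
    bb$x <- block$x[take, , drop = FALSE]
    bb$group <- block$group[take]; bb$condition <- block$condition[take]
    bb$subject <- paste0(block$subject[take], "#", seq_along(take))
    cmb <- condition_mean_matrix(bb, design)
    fit <- tryCatch(pls_svd(cmb$M), error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$v)) { dropped <- dropped + 1L; next }
    rot <- procrustes_rotation(obs$u, fit$u)
    vs[, , b] <- (fit$v %*% diag(fit$s, n_lv)) %*% rot
    scb <- sweep(cmb$M %*% (fit$v %*% rot), 2L, obs$s, "/")
    sc[, , b] <- sweep(scb, 2L, colMeans(scb))
  }
  if (dropped > 0.05 * n_boot)
    warning(dropped, " of ", n_boot, " bootstrap replicates dropped as degenerate")
  se <- apply(vs, c(1L, 2L), sd, na.rm = TRUE)
  ratios <- (obs$v %*% diag(obs$s, n_lv)) / se
  dimnames(ratios) <- dimnames(obs$v)
  lo <- apply(sc, c(1L, 2L), quantile, probs = 0.025, na.rm = TRUE)
  hi <- apply(sc, c(1L, 2L), quantile, probs = 0.975, na.rm = TRUE)
  rownames(lo) <- rownames(hi) <- rownames(cm$M)
  dimnames(sc)[[1L]] <- rownames(cm$M)
  list(ratios = ratios, score_ci_lo = lo, score_ci_hi = hi,
       score_reps = sc, cells = cm$cells,
       n_dropped = dropped, threshold = bsr_threshold())
}

#' Mean-centered Task-PLS
#'
#' Full inference pipeline: cell-mean matrix, SVD, permutation test on the
#' singular values, bootstrap element reliability, and per-observation brain
#' scores. Elements missing in more than `max_missing` of rows are dropped
#' (with a message) before decomposition; remaining missing values are
#' excluded pairwise from cell means.
#'
#' @inheritParams permutation_test
#' @param n_boot bootstrap replicates; 0 skips the bootstrap.
#' @param max_missing tolerated per-element missingness fraction.
#' @return a `pls_model`: task saliences `u`, singular values `s`, brain
#'   saliences `v`, `cov_explained`, `perm_p`, bootstrap `ratios` and score
#'   CIs, `scores`, `cell_scores_norm`, plus the settings record.
#' @export
mc_task_pls <- function(block, design, n_perm = 1000, n_boot = 500, seed = 1L,
                        scheme = c("unrestricted", "within_subject"),
                        max_missing = 0.2) {
  scheme <- match.arg(scheme)
  miss <- colMeans(is.na(block$x))
  if (any(miss > max_missing)) {
    message("dropping ", sum(miss > max_missing),
            " element(s) missing in > ", max_missing * 100, "% of rows")
    keep <- miss <= max_missing
    block <- data_block(block$x[, keep, drop = FALSE], block$subject,
                        block$group, block$condition, block$elements[keep])
  }
  cm <- condition_mean_matrix(block, design)
  if (anyNA(cm$M))
    stop_param("cell-mean matrix still has missing elements; lower max_missing")
  fit <- pls_svd(cm$M)
  model <- c(fit, list(grand_mean = cm$grand_mean, cells = cm$cells,
                       elements = block$elements))
  seeds <- derive_seeds(seed, 2L)
  perm_p <- permutation_test(block, design, n_perm = n_perm,
                             seed = seeds[1L], scheme = scheme)
  boot <- if (n_boot > 0) bootstrap_test(block, design, n_boot = n_boot,
                                         seed = seeds[2L]) else NULL
  scores <- brain_scores(block, model)
  structure(c(model,
              list(perm_p = perm_p, boot = boot, scores = scores$scores,
                   cell_scores = scores$cell_scores,
                   cell_scores_norm = scores$cell_scores_norm,
                   settings = list(n_perm = n_perm, n_boot = n_boot,
                                   seed = seed, scheme = scheme))),
            class = "pls_model")
}

#' Group-level bootstrap CIs of normalized brain scores
#'
#' Averages each group's condition cells within every bootstrap replicate and
#' returns 95% percentile intervals of the group-mean normalized brain score
#' for one latent variable. Two groups whose intervals do not overlap are
#' reliably separated by that contrast.
#'
#' @param fit a `pls_model` fitted with a bootstrap.
#' @param lv latent-variable index.
#' @return data.frame with columns `group`, `mean`, `lo`, `hi`.
#' @export
group_score_ci <- function(fit, lv = 1L) {
  if (is.null(fit$boot)) stop_param("model was fitted without a bootstrap")
  reps <- fit$boot$score_reps[, lv, , drop = TRUE]   # cells x replicates
  groups <- fit$boot$cells$group
  out <- do.call(rbind, lapply(unique(groups), function(g) {
    gm <- colMeans(reps[groups == g, , drop = FALSE])
    data.frame(group = g, mean = mean(gm, na.rm = TRUE),
               lo = quantile(gm, 0.025, na.rm = TRUE, names = FALSE),
               hi = quantile(gm, 0.975, na.rm = TRUE, names = FALSE))
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d LVs over %d elements\n", length(x$s),
              nrow(x$v)))
  df <- data.frame(LV = seq_along(x$s), singular_value = signif(x$s, 4),
                   cov_explained = signif(x$cov_explained, 4),
                   perm_p = signif(x$perm_p, 4))
  print(df, row.names = FALSE)
  invisible(x)
}
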