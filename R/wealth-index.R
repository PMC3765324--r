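#' Expand categorical asset variables into a disjunctive (indicator) matrix
#'
#' Standard preprocessing for multiple correspondence analysis: every observed
#' level of every categorical variable becomes one binary column. Variables
#' with a single observed level carry no information and are dropped with a
#' warning. Missing responses are handled per `missing`: the default
#' complete-indicator approach leaves all indicator columns of the missing
#' variable at zero (row sums then count answered variables), preserving the
#' sample; `"complete-case"` drops rows with any missing response. Rows with
#' every variable missing are always dropped.
#'
#' @param assets Data frame of categorical (or 0/1) asset variables.
#' @param missing `"indicator"` (default) or `"complete-case"`.
#' @return Binary matrix with attributes `var` (originating variable per
#'   column), `level` (level per column) and `kept_rows` (row indices of
#'   `assets` retained).
#' @export
indicator_expand <- function(assets, missing = c("indicator", "complete-case")) {
  missing <- match.arg(missing)
  assert_that(is.data.frame(assets) && ncol(assets) >= 1L,
              "`assets` must be a data frame with at least one column",
              "equicover_invalid_assets")
  fac <- lapply(assets, function(col) factor(col))
  nlev <- vapply(fac, nlevels, 1L)
  if (any(nlev < 2)) {
    warning("dropping single-level asset variable(s): ",
            paste(names(assets)[nlev < 2], collapse = ", "), call. = FALSE)
    fac <- fac[nlev >= 2]
  }
  assert_that(length(fac) >= 1L, "no asset variable has two observed levels",
              "equicover_invalid_assets")
  n <- nrow(assets)
  all_missing <- Reduce(`&`, lapply(fac, is.na))
  keep <- !all_missing
  if (missing == "complete-case") keep <- keep & !Reduce(`|`, lapply(fac, is.na))
  if (any(all_missing)) {
    warning(sum(all_missing), " row(s) with all assets missing dropped", call. = FALSE)
  }
  assert_that(any(keep), "no rows remain after missing-data handling",
              "equicover_invalid_assets")
  blocks <- lapply(names(fac), function(v) {
    f <- fac[[v]][keep]
    m <- matrix(0, sum(keep), nlevels(f),
                dimnames = list(NULL, paste(v, levels(f), sep = ":")))
    ok <- !is.na(f)
    m[cbind(which(ok), as.integer(f)[ok])] <- 1
    m
  })
  Z <- do.call(cbind, blocks)
  structure(Z,
            var = rep(names(fac), vapply(fac, nlevels, 1L)),
            level = unlist(lapply(fac, levels), use.names = FALSE),
            kept_rows = which(keep))
}

#' First dimension of (weighted) multiple correspondence analysis
#'
#' Correspondence analysis of a disjunctive indicator matrix: the matrix of
#' relative frequencies is double-centred and standardised by row and column
#' masses, and its leading singular vector gives the first-dimension standard
#' row coordinates — the asset-based living-standards score. Optional row
#' weights (survey weights) enter the row masses, so the scores have weighted
#' mean zero. The sign is normalised so the score correlates positively with
#' the per-row count of advantaged levels, making the poorest group a
#' deterministic label downstream.
#'
#' @param Z Disjunctive matrix from [indicator_expand()].
#' @param row_weights Optional positive row weights (default equal).
#' @param advantaged Optional character vector naming the advantaged level of
#'   each variable (defaults to the last factor level, e.g. `"1"` for 0/1
#'   coded ownership).
#' @return Object of class `"wealth_scores"`: list with `score` (standard row
#'   coordinates, weighted mean 0, weighted variance 1), `inertia_share` of
#'   the first dimension, `orientation` (+1/-1 applied), and the column
#'   standard coordinates `column_coord`.
#' @export
mca_first_dimension <- function(Z, row_weights = NULL, advantaged = NULL) {
  assert_that(is.matrix(Z) && nrow(Z) >= 2L && ncol(Z) >= 2L,
              "indicator matrix must have at least 2 rows and columns",
              "equicover_degenerate_assets")
  if (is.null(row_weights)) row_weights <- rep(1, nrow(Z))
  assert_that(length(row_weights) == nrow(Z) && all(row_weights > 0),
              "row weights must be positive and align with rows",
              "equicover_invalid_assets")
  if (nrow(unique(Z)) < 2) {
    abort("no variation in assets: all household profiles identical",
          "equicover_degenerate_assets")
  }
  N <- Z * row_weights
  P <- N / sum(N)
  r <- rowSums(P)
  cm <- colSums(P)
  keep_col <- cm > 0
  S <- (P[, keep_col, drop = FALSE] - outer(r, cm[keep_col])) /
    sqrt(outer(r, cm[keep_col]))
  dec <- svd(S)
  sv <- dec$d
  # the trivial dimension is removed by the double centring; guard anyway
  tol <- max(dim(S)) * max(sv) * .Machine$double.eps
  pos <- sv > tol
  assert_that(any(pos), "no variation in assets: residual matrix is null",
              "equicover_degenerate_assets")
  score <- dec$u[, 1] / sqrt(r)
  col_coord <- rep(NA_real_, ncol(Z))
  col_coord[keep_col] <- dec$v[, 1] / sqrt(cm[keep_col])
  inertia_share <- sv[1]^2 / sum(sv[pos]^2)

  vars <- attr(Z, "var")
  levs <- attr(Z, "level")
  adv_count <- advantaged_count(Z, vars, levs, advantaged)
  orientation <- 1
  wc <- weighted_cor(score, adv_count, row_weights)
  if (is.finite(wc) && wc < 0) orientation <- -1
  score <- orientation * score
  col_coord <- orientation * col_coord
  structure(list(score = score, inertia_share = inertia_share,
                 orientation = orientation,
                 column_coord = stats::setNames(col_coord, colnames(Z)),
                 singular_values = sv[pos]),
            class = "wealth_scores")
}

# Count of advantaged levels held by each row; default advantaged level is
# the last level of each variable (e.g. "1" for 0/1, "yes" for no/yes).
advantaged_count <- function(Z, vars, levs, advantaged) {
  if (is.null(vars)) return(rowSums(Z))
  sel <- logical(ncol(Z))
  for (v in unique(vars)) {
    idx <- which(vars == v)
    lev <- if (!is.null(advantaged) && v %in% names(advantaged)) {
      advantaged[[v]]
    } else {
      levs[idx[length(idx)]]
    }
    hit <- idx[levs[idx] == lev]
    if (length(hit)) sel[hit[1]] <- TRUE
  }
  rowSums(Z[, sel, drop = FALSE])
}

weighted_cor <- function(x, y, w) {
  w <- w / sum(w)
  mx <- sum(w * x); my <- sum(w * y)
  vx <- sum(w * (x - mx)^2); vy <- sum(w * (y - my)^2)
  if (vx <= 0 || vy <= 0) return(NA_real_)
  sum(w * (x - mx) * (y - my)) / sqrt(vx * vy)
}

#' Assign weighted quantile groups from wealth scores
#'
#' Orders households by score and cuts the cumulative weight distribution at
#' fractions `j/k`. A household falling exactly on a boundary goes to the
#' lower group; tied scores are never split across groups (the boundary moves
#' to the end of the tie). Group shares are recomputed from the final
#' assignment, so they equal `1/k` only in the untied, equal-weight case.
#'
#' @param score Numeric wealth score per household (higher = better off).
#' @param weights Positive weights (default equal).
#' @param k Number of groups (default 4, quartiles).
#' @return Object of class `"quantile_assignment"`: list with `group` (ordered
#'   factor, `QI` = poorest), `k`, and `shares` (weighted, summing to 1).
#' @export
assign_quantile_groups <- function(score, weights = NULL, k = 4) {
  assert_that(is_count(k) && k >= 2, "`k` must be an integer >= 2",
              "equicover_infeasible_grouping")
  n <- length(score)
  if (is.null(weights)) weights <- rep(1, n)
  assert_that(length(weights) == n && all(weights > 0),
              "weights must be positive and align with scores",
              "equicover_invalid_design")
  if (length(unique(score)) < k) {
    abort(sprintf("cannot form %d groups from %d distinct scores", k,
                  length(unique(score))), "equicover_infeasible_grouping")
  }
  ord <- order(score)
  W <- sum(weights)
  cw <- cumsum(weights[ord])
  # group of each sorted household by its cumulative weight; exact boundary
  # (within machine tolerance) stays in the lower group
  g_sorted <- ceiling(cw * k / W - 1e-12)
  g_sorted[g_sorted < 1] <- 1L
  g_sorted[g_sorted > k] <- k
  # ties: every copy of a score takes the group of the tie's last member
  s_sorted <- score[ord]
  last_of_run <- rev(!duplicated(rev(s_sorted)))
  g_sorted <- rev(cummin(rev(ifelse(last_of_run, g_sorted, k))))
  g <- integer(n)
  g[ord] <- g_sorted
  labels <- quantile_labels(k)
  if (length(unique(g)) < k) {
    abort("ties in scores leave at least one quantile group empty",
          "equicover_infeasible_grouping")
  }
  group <- factor(labels[g], levels = labels, ordered = TRUE)
  shares <- as.numeric(tapply(weights, group, sum) / W)
  structure(list(group = group, k = k,
                 shares = stats::setNames(shares, labels)),
            class = "quantile_assignment")
}

#' Asset-based wealth index: MCA scores plus weighted quantile groups
#'
#' Convenience wrapper running [indicator_expand()], [mca_first_dimension()]
#' and [assign_quantile_groups()] in sequence on a household asset table.
#'
#' @inheritParams indicator_expand
#' @inheritParams mca_first_dimension
#' @param weights Optional household weights, used both in the MCA row masses
#'   (weighted MCA; set `weighted_mca = FALSE` to exclude them there) and in
#'   the quantile cut.
#' @param k Number of socio-economic groups (default 4).
#' @param weighted_mca Use the weights in the MCA row masses (default TRUE).
#' @return List with `score` (aligned to `assets` rows, `NA` for dropped
#'   rows), `group`, `mca` (the `"wealth_scores"` object), `assignment` and
#'   `kept_rows`.
#' @export
wealth_index <- function(assets, weights = NULL, k = 4,
                         missing = "indicator", advantaged = NULL,
                         weighted_mca = TRUE) {
  Z <- indicator_expand(assets, missing = missing)
  kept <- attr(Z, "kept_rows")
  w <- if (is.null(weights)) rep(1, length(kept)) else weights[kept]
  mca <- mca_first_dimension(Z, row_weights = if (weighted_mca) w else NULL,
                             advantaged = advantaged)
  assignment <- assign_quantile_groups(mca$score, weights = w, k = k)
  score <- rep(NA_real_, nrow(assets))
  score[kept] <- mca$score
  group <- factor(rep(NA_character_, nrow(assets)),
                  levels = levels(assignment$group), ordered = TRUE)
  group[kept] <- assignment$group
  list(score = score, group = group, mca = mca, assignment = assignment,
       kept_rows = kept)
}
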