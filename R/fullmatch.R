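# Optimal full matching with replacement under a propensity caliper.
#
# Subclasses contain one treated with >= 1 controls or one control with >= 2
# treated; every on-support unit with at least one caliper-admissible partner
# appears in a subclass, and the total within-subclass Mahalanobis distance
# is minimised. With distances >= 0 this is exactly the minimum-cost edge
# cover of the caliper-admissible bipartite graph, solved by the classical
# reduction: per-vertex cheapest edge + minimum-cost matching over
# negative-reduced-cost edges (successive shortest augmenting paths), then
# removal of redundant edges so every component is a star.

# pairwise Mahalanobis distances between rows of A and rows of B
mahalanobis_pairs <- function(A, B, Sinv) {
  out <- matrix(0, nrow(A), nrow(B))
  for (j in seq_len(nrow(B))) {
    d <- sweep(A, 2, B[j, ])
    out[, j] <- sqrt(pmax(rowSums((d %*% Sinv) * d), 0))
  }
  out
}

# Minimum-cost matching restricted to edges with negative cost, by
# multi-source Bellman-Ford successive shortest paths. `R` is an nt x nc
# cost matrix with NA for absent edges. Returns a logical nt x nc matrix.
min_cost_neg_matching <- function(R) {
  nt <- nrow(R); nc <- ncol(R)
  M <- matrix(FALSE, nt, nc)
  has_edge <- !is.na(R) & R < 0
  if (!any(has_edge)) return(M)
  Rn <- R
  Rn[!has_edge] <- NA
  repeat {
    row_matched <- rowSums(M) > 0
    col_matched <- colSums(M) > 0
    Rfwd <- Rn
    Rfwd[M] <- NA # matched edges are only traversable backwards
    dt <- ifelse(row_matched, Inf, 0)
    dc <- rep(Inf, nc)
    # Bellman-Ford over the alternating structure
    for (iter in seq_len(2L * min(nt, nc) + 2L)) {
      changed <- FALSE
      # free edges t -> c
      cand <- sweep(Rfwd, 1, dt, `+`)  # dt[i] + R[i, j]
      newdc <- suppressWarnings(apply(cand, 2, min, na.rm = TRUE))
      newdc[!is.finite(newdc)] <- Inf
      upd <- newdc < dc - 1e-12
      if (any(upd)) { dc[upd] <- newdc[upd]; changed <- TRUE }
      # matched edges c -> t (traverse backwards, refund the cost)
      mi <- which(M, arr.ind = TRUE)
      if (nrow(mi)) {
        back <- dc[mi[, 2]] - R[mi]
        upd <- back < dt[mi[, 1]] - 1e-12
        if (any(upd)) { dt[mi[upd, 1]] <- back[upd]; changed <- TRUE }
      }
      if (!changed) break
    }
    free_c <- which(!col_matched & is.finite(dc))
    if (!length(free_c)) break
    end <- free_c[which.min(dc[free_c])]
    if (dc[end] >= -1e-12) break
    # backtrack the augmenting path and flip it
    j <- end
    repeat {
      i <- which(abs(dt + Rfwd[, j] - dc[j]) < 1e-9 & !M[, j])[1]
      if (is.na(i)) stop("internal error: augmenting path backtrack failed")
      M[i, j] <- TRUE
      jprev <- which(M[i, ] & seq_len(nc) != j)
      was_matched <- FALSE
      for (j2 in jprev) {
        if (abs((dc[j2] - R[i, j2]) - dt[i]) < 1e-9) {
          M[i, j2] <- FALSE
          j <- j2
          was_matched <- TRUE
          break
        }
      }
      if (!was_matched) {
        if (length(jprev)) { # matched row reached via a non-tight edge: undo
          M[i, jprev[1]] <- FALSE
          j <- jprev[1]
        } else break
      }
    }
  }
  M
}

#' Optimal full matching for one contrast
#'
#' @param fit a `propensity_fit`.
#' @param bounds support bounds from [trim_support()]; `NULL` skips trimming
#'   (the unrestricted analysis).
#' @param metrics areal-weighted metric table (for the Mahalanobis
#'   covariates `pct_nonwhite` and `median_home_value`).
#' @param caliper_sd caliper as a multiple of the propensity SD in the
#'   on-support contrast sample (default 0.2, on the raw propensity scale).
#' @param mahal_covariates covariates of the within-caliper distance.
#' @return A `matched_sample`: `subclasses` (list of treated/control id
#'   sets), `weights` (data.frame `polygon_id`, `weight`, `role`,
#'   `subclass`), `caliper`, `total_distance`, `discarded` (units with no
#'   admissible partner).
#' @export
full_match <- function(fit, bounds, metrics, caliper_sd = 0.2,
                       mahal_covariates = c("pct_nonwhite", "median_home_value")) {
  keep <- if (is.null(bounds)) rep(TRUE, length(fit$polygon_id))
          else fit$polygon_id %in% bounds$retained
  ids <- fit$polygon_id[keep]
  ps <- fit$propensity[keep]
  trt <- fit$treated[keep]
  if (sum(trt == 1) < 2L || sum(trt == 0) < 2L)
    stop("need at least 2 on-support neighborhoods per arm")
  X <- as.matrix(metrics[match(ids, metrics$polygon_id), mahal_covariates, drop = FALSE])
  if (anyNA(X)) stop("missing Mahalanobis covariates")
  S <- stats::cov(X) + diag(1e-8, ncol(X))
  Sinv <- solve(S)
  caliper <- caliper_sd * stats::sd(ps)
  ti <- which(trt == 1); ci <- which(trt == 0)
  D <- mahalanobis_pairs(X[ti, , drop = FALSE], X[ci, , drop = FALSE], Sinv)
  adm <- abs(outer(ps[ti], ps[ci], `-`)) <= caliper + 1e-12
  drop_t <- rowSums(adm) == 0
  drop_c <- colSums(adm) == 0
  discarded <- data.frame(
    polygon_id = c(ids[ti[drop_t]], ids[ci[drop_c]]),
    role = c(rep("treated", sum(drop_t)), rep("control", sum(drop_c))),
    stringsAsFactors = FALSE)
  ti <- ti[!drop_t]; ci <- ci[!drop_c]
  if (!length(ti) || !length(ci)) stop("caliper admits no matches")
  D <- D[!drop_t, !drop_c, drop = FALSE]
  adm <- adm[!drop_t, !drop_c, drop = FALSE]
  Dm <- D
  Dm[!adm] <- NA
  # reduction: cheapest incident edge per vertex, matching on reduced costs
  mt <- apply(Dm, 1, min, na.rm = TRUE)
  mc <- apply(Dm, 2, min, na.rm = TRUE)
  Rred <- sweep(sweep(Dm, 1, mt), 2, mc)
  M <- min_cost_neg_matching(Rred)
  cover <- M
  for (i in which(rowSums(M) == 0)) cover[i, which.min(Dm[i, ])] <- TRUE
  for (j in which(colSums(cover) == 0)) cover[which.min(Dm[, j]), j] <- TRUE
  # star-ify: drop (most expensive first) edges whose endpoints both have
  # other edges; cost never increases, cover is preserved
  repeat {
    deg_t <- rowSums(cover); deg_c <- colSums(cover)
    bad <- which(cover & outer(deg_t > 1, deg_c > 1, `&`), arr.ind = TRUE)
    if (!nrow(bad)) break
    worst <- bad[which.max(Dm[bad]), , drop = FALSE]
    cover[worst] <- FALSE
  }
  # components are stars: build subclasses
  deg_t <- rowSums(cover)
  subclasses <- list()
  used_c <- rep(FALSE, length(ci))
  for (i in seq_along(ti)) {
    js <- which(cover[i, ])
    if (length(js) == 0) next
    if (deg_t[i] >= 1 && all(colSums(cover)[js] == 1)) {
      # star centred on treated i (or a 1:1 pair)
      subclasses[[length(subclasses) + 1L]] <-
        list(treated = ids[ti[i]], control = ids[ci[js]])
      used_c[js] <- TRUE
    }
  }
  for (j in which(colSums(cover) > 1)) {
    is <- which(cover[, j])
    subclasses[[length(subclasses) + 1L]] <-
      list(treated = ids[ti[is]], control = ids[ci[j]])
    used_c[j] <- TRUE
  }
  # weights: treated 1; controls share their subclass's treated count
  wrows <- list()
  for (k in seq_along(subclasses)) {
    s <- subclasses[[k]]
    wrows[[length(wrows) + 1L]] <- data.frame(
      polygon_id = c(s$treated, s$control),
      weight = c(rep(1, length(s$treated)),
                 rep(length(s$treated) / length(s$control), length(s$control))),
      role = c(rep("treated", length(s$treated)), rep("control", length(s$control))),
      subclass = k, stringsAsFactors = FALSE)
  }
  weights <- do.call(rbind, wrows)
  agg <- stats::aggregate(weight ~ polygon_id + role, data = weights, FUN = sum)
  structure(list(subclasses = subclasses, weights = weights,
                 unit_weights = agg, caliper = caliper,
                 total_distance = sum(Dm[cover]),
                 discarded = discarded,
                 mahal_covariates = mahal_covariates),
            class = "matched_sample")
}

#' Propagate neighborhood matching weights to births
#'
#' @param match a `matched_sample`.
#' @param assignments birth-to-polygon assignment table (from
#'   [assign_grade()] or a cohort carrying `polygon_id`).
#' @return Numeric vector of per-birth weights (0 for births in unmatched,
#'   trimmed, NG or outside-map neighborhoods), aligned with the rows of
#'   `assignments`.
#' @export
assign_birth_weights <- function(match, assignments) {
  uw <- match$unit_weights
  idx <- match(assignments$polygon_id, uw$polygon_id)
  w <- uw$weight[idx]
  w[is.na(w)] <- 0
  w
}
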