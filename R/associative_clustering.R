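#' Iterative outlier screen for one burst's trials
#'
#' Generalized ESD-style trimming in the spirit of Rosner's test: at each
#' iteration the trial with the largest deviation from the current mean, in
#' SD units of either coordinate, is removed if that deviation exceeds
#' `margin` SD; means and SDs are recomputed after every removal. Screening
#' stops when no trial exceeds the margin or when 10% of the original trials
#' have been removed. Deviations are assessed per coordinate (onset and
#' offset separately), taking the larger of the two; ties go to the earliest
#' trial, so the procedure is deterministic.
#'
#' @param onset,offset numeric vectors of equal length, one entry per trial.
#' @param margin outlier margin in SD units (default 2).
#' @param max_frac maximum fraction of trials that may be removed (default 0.1).
#' @return list with elements `onset`, `offset` (retained trials), `kept`
#'   (logical index into the input) and `removed` (count).
#' @export
screen_outliers <- function(onset, offset, margin = 2, max_frac = 0.1) {
  stopifnot(length(onset) == length(offset))
  n0 <- length(onset)
  kept <- rep(TRUE, n0)
  if (n0 < 3L) {
    message("fewer than 3 trials: outlier screen skipped")
    return(list(onset = onset, offset = offset, kept = kept, removed = 0L))
  }
  max_rm <- floor(max_frac * n0)
  removed <- 0L
  while (removed < max_rm) {
    on <- onset[kept]
    off <- offset[kept]
    sx <- stats::sd(on)
    sy <- stats::sd(off)
    dx <- if (sx > 0) abs(on - mean(on)) / sx else rep(0, length(on))
    dy <- if (sy > 0) abs(off - mean(off)) / sy else rep(0, length(off))
    dev <- pmax(dx, dy)
    worst <- which.max(dev)
    if (dev[worst] <= margin) break
    kept[which(kept)[worst]] <- FALSE
    removed <- removed + 1L
  }
  list(onset = onset[kept], offset = offset[kept], kept = kept, removed = removed)
}

#' Phase-plane summary statistics of one burst
#'
#' Sample mean vector P = (X, Y), sample SD vector S = (sX, sY) (n - 1
#' denominator) and sample correlation of (onset, offset) across trials.
#' For degenerate bursts (zero variance in either coordinate) the correlation
#' is defined as 0.
#'
#' @param label burst label (e.g. `"Bic(1)"`).
#' @param onset,offset per-trial phases; at least 2 trials required.
#' @return one-row data.frame of class `burst_stats` with columns
#'   `label`, `X`, `Y`, `sX`, `sY`, `rho`, `n`.
#' @export
summarize_burst <- function(label, onset, offset) {
  stopifnot(length(onset) == length(offset))
  n <- length(onset)
  if (n < 2L) stop("insufficient data: at least 2 trials needed for burst '", label, "'")
  sx <- stats::sd(onset)
  sy <- stats::sd(offset)
  rho <- if (sx > 0 && sy > 0) stats::cor(onset, offset) else 0
  out <- data.frame(
    label = label, X = mean(onset), Y = mean(offset),
    sX = sx, sY = sy, rho = rho, n = n,
    stringsAsFactors = FALSE
  )
  class(out) <- c("burst_stats", "data.frame")
  out
}

#' Summarize every burst of a burst table
#'
#' Groups trials by `burst_label`, optionally screens outliers per burst with
#' [screen_outliers()], and returns one [summarize_burst()] row per burst,
#' ordered by ascending mean onset.
#'
#' @param bt a [burst_table()] (typically one condition).
#' @param screen apply the outlier screen first? (default TRUE)
#' @param margin outlier margin in SD units.
#' @return `burst_stats` data.frame; attribute `outliers_removed` gives the
#'   total count removed.
#' @export
summarize_bursts <- function(bt, screen = TRUE, margin = 2) {
  labels <- sort(unique(bt$burst_label))
  removed <- 0L
  rows <- lapply(labels, function(lb) {
    tr <- bt[bt$burst_label == lb, ]
    # canonical trial order: summaries identical under input-row permutation
    tr <- tr[order(tr$cycle_index, tr$onset, tr$offset), ]
    on <- tr$onset
    off <- tr$offset
    if (screen && length(on) >= 3L) {
      sc <- screen_outliers(on, off, margin = margin)
      removed <<- removed + sc$removed
      on <- sc$onset
      off <- sc$offset
    }
    summarize_burst(lb, on, off)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$X, out$label), ]
  rownames(out) <- NULL
  class(out) <- c("burst_stats", "data.frame")
  attr(out, "outliers_removed") <- removed
  out
}

#' Phase-plane adjacency criterion between two bursts
#'
#' Each burst is represented by the rectangle of +/-1 SD around its centroid.
#' The criterion projects, for each burst, the SD vertex vector onto the unit
#' inter-centroid axis (taking the vertex sign combination that maximizes the
#' projection, i.e. the vertex facing the neighbour) and subtracts the
#' centroid distance:
#' \deqn{q = (|\sigma_{Xa} \hat d_x| + |\sigma_{Ya} \hat d_y|) +
#'           (|\sigma_{Xb} \hat d_x| + |\sigma_{Yb} \hat d_y|) - \|d\|}
#' `q > 0` means the two rectangles' projections onto the inter-centroid axis
#' overlap and the bursts are candidates for the same cluster. Identical
#' centroids return `Inf` (adjacent by convention).
#'
#' @param a,b one-row `burst_stats` (or any list with `X`, `Y`, `sX`, `sY`).
#' @return the q value, in phase units.
#' @export
adjacency_q <- function(a, b) {
  d <- c(a$X - b$X, a$Y - b$Y)
  nd <- sqrt(sum(d^2))
  if (nd == 0) return(Inf)
  dh <- d / nd
  proj_a <- abs(a$sX * dh[1L]) + abs(a$sY * dh[2L])
  proj_b <- abs(b$sX * dh[1L]) + abs(b$sY * dh[2L])
  proj_a + proj_b - nd
}

#' Boolean adjacency matrix over all burst pairs
#'
#' Evaluates [adjacency_q()] for every pair and records whether `q > 0`.
#' The matrix is symmetric with a `TRUE` diagonal.
#'
#' @param stats `burst_stats` data.frame with unique labels.
#' @return logical matrix with dimnames = burst labels.
#' @export
build_adjacency <- function(stats) {
  n <- nrow(stats)
  if (n < 1L) stop("need at least one burst")
  if (anyDuplicated(stats$label)) stop("duplicate burst labels")
  B <- diag(n) > 0
  dimnames(B) <- list(stats$label, stats$label)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        q <- adjacency_q(stats[i, ], stats[j, ])
        B[i, j] <- B[j, i] <- q > 0
      }
    }
  }
  B
}

#' Equivalence classes of the adjacency graph
#'
#' Union-find merging of all adjacent pairs, giving the connected components
#' (transitive closure) of the adjacency graph: the clusters.
#'
#' @param adj logical adjacency matrix from [build_adjacency()].
#' @return named integer vector mapping each label to a class id (numbered by
#'   first appearance in the matrix order).
#' @export
equivalence_classes <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        if (isTRUE(adj[i, j]) || isTRUE(adj[j, i])) {
          ri <- find(i)
          rj <- find(j)
          if (ri != rj) parent[rj] <- ri
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  ids <- match(roots, unique(roots))
  names(ids) <- rownames(adj)
  ids
}

# Trial-weighted pooled (onset, offset) statistics over member bursts,
# combined exactly from per-burst sufficient statistics.
pool_stats <- function(rows) {
  N <- sum(rows$n)
  mx <- sum(rows$n * rows$X) / N
  my <- sum(rows$n * rows$Y) / N
  if (N < 2L) {
    return(list(X = mx, sX = 0, Y = my, sY = 0, rho = 0, n = N))
  }
  ssx <- sum((rows$n - 1) * rows$sX^2 + rows$n * (rows$X - mx)^2)
  ssy <- sum((rows$n - 1) * rows$sY^2 + rows$n * (rows$Y - my)^2)
  sxy <- sum((rows$n - 1) * rows$rho * rows$sX * rows$sY +
               rows$n * (rows$X - mx) * (rows$Y - my))
  sx <- sqrt(ssx / (N - 1))
  sy <- sqrt(ssy / (N - 1))
  rho <- if (sx > 0 && sy > 0) sxy / ((N - 1) * sx * sy) else 0
  list(X = mx, sX = sx, Y = my, sY = sy, rho = rho, n = N)
}

#' Order a partition into a cluster solution
#'
#' Renumbers clusters so ids 1..K proceed by ascending cluster mean onset
#' (the unweighted mean of member burst centroids' X). Ties are broken by the
#' lexicographically first member label, making the ordering deterministic
#' under any permutation of the input. Each cluster carries its unweighted
#' centroid and trial-weighted pooled statistics.
#'
#' @param partition named integer vector (label -> class) or list of member
#'   label vectors.
#' @param stats `burst_stats` covering every label in the partition.
#' @param mode `"unconstrained"` or `"constrained"`.
#' @return object of class `cluster_solution`.
#' @export
order_clusters <- function(partition, stats, mode = "unconstrained") {
  if (!is.list(partition)) {
    partition <- split(names(partition), partition)
  }
  members <- lapply(partition, function(m) sort(as.character(m)))
  if (!all(unlist(members) %in% stats$label)) {
    stop("partition refers to labels missing from stats")
  }
  mean_onset <- vapply(members, function(m) {
    mean(stats$X[match(m, stats$label)])
  }, numeric(1))
  first_label <- vapply(members, function(m) m[1L], character(1))
  ord <- order(mean_onset, first_label)
  clusters <- lapply(seq_along(ord), function(k) {
    m <- members[[ord[k]]]
    rows <- stats[match(m, stats$label), ]
    m <- m[order(rows$X[match(m, rows$label)], m)]
    rows <- stats[match(m, stats$label), ]
    list(
      id = k,
      members = m,
      centroid = c(X = mean(rows$X), Y = mean(rows$Y)),
      pooled = pool_stats(rows)
    )
  })
  structure(list(mode = mode, clusters = clusters), class = "cluster_solution")
}

#' Unconstrained associative clustering
#'
#' Single-stage pipeline: adjacency matrix, equivalence classes, onset
#' ordering.
#'
#' @param stats `burst_stats` data.frame.
#' @return a `cluster_solution`.
#' @export
cluster_bursts <- function(stats) {
  order_clusters(equivalence_classes(build_adjacency(stats)), stats)
}

#' Two-substage associative clustering
#'
#' Stage 1 clusters the primary dataset (the most complete animal) alone.
#' Stage 2 takes additional bursts in ascending mean-onset order; each may join
#' an existing cluster or start a new one. A candidate joins a multi-member
#' cluster only if it is adjacent (`q > 0`) to at least two of its members; a
#' singleton cluster requires one adjacency. If several clusters qualify the
#' one with the most adjacent members wins, ties broken by smallest centroid
#' distance. Bursts joining nothing are clustered among themselves by ordinary
#' adjacency and appended as new clusters. Final ids are reordered by onset.
#'
#' @param primary_stats,additional_stats `burst_stats` with disjoint labels.
#' @return a `cluster_solution`.
#' @export
cluster_two_stage <- function(primary_stats, additional_stats) {
  if (length(intersect(primary_stats$label, additional_stats$label))) {
    stop("primary and additional label sets must be disjoint")
  }
  stage1 <- cluster_bursts(primary_stats)
  groups <- lapply(stage1$clusters, `[[`, "members")
  if (nrow(additional_stats) == 0L) return(stage1)

  all_stats <- rbind(as.data.frame(primary_stats), as.data.frame(additional_stats))
  add <- additional_stats[order(additional_stats$X, additional_stats$label), ]
  leftovers <- character(0)
  for (i in seq_len(nrow(add))) {
    cand <- add[i, ]
    n_adj <- vapply(groups, function(m) {
      sum(vapply(m, function(lb) {
        adjacency_q(cand, all_stats[all_stats$label == lb, ]) > 0
      }, logical(1)))
    }, integer(1))
    need <- ifelse(lengths(groups) > 1L, 2L, 1L)
    ok <- which(n_adj >= need)
    if (length(ok) == 0L) {
      leftovers <- c(leftovers, cand$label)
    } else {
      if (length(ok) > 1L) {
        best <- ok[n_adj[ok] == max(n_adj[ok])]
        if (length(best) > 1L) {
          cd <- vapply(best, function(g) {
            rows <- all_stats[match(groups[[g]], all_stats$label), ]
            sqrt((mean(rows$X) - cand$X)^2 + (mean(rows$Y) - cand$Y)^2)
          }, numeric(1))
          best <- best[which.min(cd)]
        }
        ok <- best[1L]
      }
      groups[[ok]] <- sort(c(groups[[ok]], cand$label))
    }
  }
  if (length(leftovers)) {
    lo_stats <- add[match(leftovers, add$label), ]
    class(lo_stats) <- c("burst_stats", "data.frame")
    lo_part <- equivalence_classes(build_adjacency(lo_stats))
    groups <- c(groups, split(names(lo_part), lo_part))
  }
  all_class <- all_stats
  class(all_class) <- c("burst_stats", "data.frame")
  order_clusters(groups, all_class)
}

#' Constrained cluster assignment against a reference solution
#'
#' Bursts whose labels occur in the reference keep their reference cluster
#' membership regardless of where their centroids moved; this is the
#' constrained mode used to compare the same synergies across conditions.
#' Novel bursts (absent from the reference) are assigned via the adjacency
#' matrix: each goes to the cluster with the greatest number of adjacent
#' (`q > 0`) members, ties broken by smallest centroid distance; a novel burst
#' adjacent to no cluster falls back to the nearest centroid with a warning.
#' Cluster ids keep the reference ordering; pooled statistics are recomputed
#' from the condition's own trials.
#'
#' @param condition_stats `burst_stats` for the condition under analysis.
#' @param reference a `cluster_solution` (typically from the unobstructed
#'   condition).
#' @return a `cluster_solution` with `mode = "constrained"`.
#' @export
assign_constrained <- function(condition_stats, reference) {
  stopifnot(inherits(reference, "cluster_solution"))
  ref_members <- lapply(reference$clusters, `[[`, "members")
  groups <- lapply(ref_members, function(m) intersect(m, condition_stats$label))
  novel <- setdiff(condition_stats$label, unlist(ref_members))
  if (length(novel)) {
    nv <- condition_stats[match(novel, condition_stats$label), ]
    nv <- nv[order(nv$X, nv$label), ]
    for (i in seq_len(nrow(nv))) {
      cand <- nv[i, ]
      n_adj <- vapply(groups, function(m) {
        if (!length(m)) return(0L)
        sum(vapply(m, function(lb) {
          adjacency_q(cand, condition_stats[condition_stats$label == lb, ]) > 0
        }, logical(1)))
      }, integer(1))
      cd <- vapply(groups, function(m) {
        if (!length(m)) return(Inf)
        rows <- condition_stats[match(m, condition_stats$label), ]
        sqrt((mean(rows$X) - cand$X)^2 + (mean(rows$Y) - cand$Y)^2)
      }, numeric(1))
      if (max(n_adj) == 0L) {
        warning(sprintf("novel burst '%s' adjacent to no cluster; assigned to nearest centroid",
                        cand$label))
        pick <- which.min(cd)
      } else {
        best <- which(n_adj == max(n_adj))
        pick <- best[which.min(cd[best])]
      }
      groups[[pick]] <- sort(c(groups[[pick]], cand$label))
    }
  }
  keep <- lengths(groups) > 0L
  groups <- groups[keep]
  clusters <- lapply(seq_along(groups), function(k) {
    m <- groups[[k]]
    rows <- condition_stats[match(m, condition_stats$label), ]
    m <- m[order(rows$X[match(m, rows$label)], m)]
    rows <- condition_stats[match(m, condition_stats$label), ]
    list(
      id = k,
      members = m,
      centroid = c(X = mean(rows$X), Y = mean(rows$Y)),
      pooled = pool_stats(rows)
    )
  })
  structure(list(mode = "constrained", clusters = clusters,
                 reference_ids = which(keep)),
            class = "cluster_solution")
}

#' Euclidean distance between two cluster centroids
#'
#' @param c1,c2 cluster entries of a `cluster_solution` (lists with a
#'   `centroid` element) or bare length-2 numeric centroids.
#' @return distance in the (onset, offset) phase plane.
#' @export
centroid_distance <- function(c1, c2) {
  p1 <- if (is.list(c1)) c1$centroid else c1
  p2 <- if (is.list(c2)) c2$centroid else c2
  sqrt(sum((p1 - p2)^2))
}

#' Partition implied by a cluster solution
#'
#' @param solution a `cluster_solution`.
#' @return named integer vector mapping burst labels to cluster ids.
#' @export
membership <- function(solution) {
  stopifnot(inherits(solution, "cluster_solution"))
  ids <- rep(vapply(solution$clusters, `[[`, integer(1), "id"),
             lengths(lapply(solution$clusters, `[[`, "members")))
  labels <- unlist(lapply(solution$clusters, `[[`, "members"))
  stats::setNames(ids, labels)[order(labels)]
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("cluster_solution (%s): %d clusters over %d bursts\n",
              x$mode, length(x$clusters), length(unlist(lapply(x$clusters, `[[`, "members")))))
  for (cl in x$clusters) {
    cat(sprintf("  #%d [X=%.3f, Y=%.3f] %s\n", cl$id,
                cl$centroid[["X"]], cl$centroid[["Y"]],
                paste(cl$members, collapse = ", ")))
  }
  invisible(x)
}
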