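#' Group-by-individual matrix of adult females
#'
#' Converts grouped detections into the binary group-by-individual (GBI)
#' matrix underlying gambit-of-the-group association indices: one row per
#' observed group containing at least one adult female, one column per
#' adult female.
#'
#' @param detections Detection tibble with `id`, `occasion`, `group_id`.
#' @param adult_ids Ids to treat as adult females; default
#'   [adult_females()].
#' @param min_sightings Drop adults seen in fewer than this many groups
#'   (default 0 = keep all).
#' @return An object of class `gbi`: list with `matrix` (groups x ids,
#'   0/1), `occasion` (integer per row), `group_id` (per row), `ids`
#'   (column order).
#' @export
build_gbi <- function(detections, adult_ids = NULL, min_sightings = 0) {
  d <- as_tibble(detections)
  adult_ids <- sort(adult_ids %||% adult_females(d))
  if (length(adult_ids) == 0L) abort("No adult females in the detection table.")
  da <- d |> filter(.data$id %in% adult_ids)
  if (nrow(da) == 0L) abort("No detections of adult females.")
  groups <- da |>
    distinct(.data$group_id, .data$occasion) |>
    arrange(.data$occasion, .data$group_id)
  m <- matrix(0L, nrow = nrow(groups), ncol = length(adult_ids),
              dimnames = list(groups$group_id, adult_ids))
  m[cbind(match(da$group_id, groups$group_id), match(da$id, adult_ids))] <- 1L
  if (min_sightings > 0) {
    keep <- colSums(m) >= min_sightings
    m <- m[, keep, drop = FALSE]
    nonempty <- rowSums(m) > 0
    m <- m[nonempty, , drop = FALSE]
    groups <- groups[nonempty, ]
  }
  structure(
    list(matrix = m, occasion = groups$occasion,
         group_id = groups$group_id, ids = colnames(m)),
    class = "gbi"
  )
}

#' @export
print.gbi <- function(x, ...) {
  cat(sprintf("<gbi> %d groups x %d adult females over %d occasions\n",
              nrow(x$matrix), ncol(x$matrix), length(unique(x$occasion))))
  invisible(x)
}

#' Simple-ratio association index matrix
#'
#' For each dyad, SRI = x / (x + y_ab + y_a + y_b), with x the number of
#' groups containing both individuals, y_ab the number of occasions on
#' which both were sighted but in different groups, and y_a/y_b the
#' occasions where only one was sighted. Since each individual appears in
#' at most one group per occasion, the denominator equals the number of
#' occasions on which at least one member of the dyad was sighted. Dyads
#' never sighted on a common sampling scale (0/0) are defined as 0.
#'
#' @param gbi A [build_gbi()] object.
#' @return A symmetric numeric matrix in \[0, 1\] with zero diagonal, ids
#'   as dimnames.
#' @export
simple_ratio_index <- function(gbi) {
  stopifnot(inherits(gbi, "gbi"))
  m <- gbi$matrix
  if (ncol(m) < 2L) abort("Need at least 2 individuals for association indices.")
  x <- crossprod(m) # same-group co-occurrence counts
  occ <- sort(unique(gbi$occasion))
  B <- matrix(0L, nrow = length(occ), ncol = ncol(m),
              dimnames = list(occ, colnames(m)))
  for (k in seq_along(occ)) {
    rows <- gbi$occasion == occ[k]
    B[k, ] <- as.integer(colSums(m[rows, , drop = FALSE]) > 0)
  }
  D <- crossprod(B) # occasions with both detected
  n_i <- diag(D)
  den <- outer(n_i, n_i, `+`) - D # occasions with either detected
  sri <- ifelse(den > 0, x / den, 0)
  diag(sri) <- 0
  sri
}

#' Partition the adult-female network into social communities
#'
#' Greedy agglomerative modularity maximization (deterministic lowest-index
#' merging) followed by a deterministic local refinement sweep that moves
#' single nodes (in id order) to the neighbouring community with the
#' largest modularity gain until no move improves weighted Newman
#' modularity Q. The result is fully determined by the association matrix
#' and the seed.
#'
#' @param assoc Symmetric nonnegative association matrix with id dimnames
#'   (e.g. from [simple_ratio_index()]).
#' @param seed Integer seed (stored; the algorithm is deterministic).
#' @param refine Run the local refinement sweep (default `TRUE`).
#' @return An object of class `community_partition`: list with
#'   `membership` (tibble `id`, `community`), `modularity`,
#'   `n_communities`, `seed`.
#' @export
detect_communities <- function(assoc, seed = 1L, refine = TRUE) {
  if (is.null(dim(assoc)) || nrow(assoc) == 0L) abort("Empty association matrix.")
  if (!isSymmetric(unname(assoc), tol = 1e-8)) abort("Association matrix must be symmetric.")
  if (any(assoc < 0)) abort("Association matrix must be nonnegative.")
  if (sum(assoc) == 0) abort("Empty network: no nonzero associations.")
  ids <- rownames(assoc) %||% as.character(seq_len(nrow(assoc)))
  set.seed(seed)
  g <- igraph::graph_from_adjacency_matrix(assoc, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  fg <- igraph::cluster_fast_greedy(g, weights = igraph::E(g)$weight)
  mem <- igraph::membership(fg)
  if (refine) mem <- refine_partition(assoc, as.integer(mem))
  # stable labels: 1..K in order of first appearance along the id order
  mem <- as.integer(factor(mem, levels = unique(mem)))
  Q <- weighted_modularity(assoc, mem)
  structure(
    list(
      membership = tibble(id = ids, community = mem),
      modularity = Q,
      n_communities = length(unique(mem)),
      seed = as.integer(seed)
    ),
    class = "community_partition"
  )
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("<community_partition> %d communities over %d adult females, Q = %.3f\n",
              x$n_communities, nrow(x$membership), x$modularity))
  invisible(x)
}

## weighted Newman modularity of a labelled partition
weighted_modularity <- function(assoc, mem) {
  diag(assoc) <- 0
  m2 <- sum(assoc) # = 2m
  if (m2 == 0) return(0)
  k <- rowSums(assoc)
  labs <- unique(mem)
  sum(vapply(labs, function(l) {
    in_l <- mem == l
    sum(assoc[in_l, in_l]) / m2 - (sum(k[in_l]) / m2)^2
  }, numeric(1)))
}

## single-node moves in id order until no improving move remains
refine_partition <- function(assoc, mem, max_passes = 10L) {
  diag(assoc) <- 0
  m2 <- sum(assoc)
  k <- rowSums(assoc)
  for (pass in seq_len(max_passes)) {
    moved <- FALSE
    for (v in seq_len(nrow(assoc))) {
      a <- as.character(mem[v])
      w_to <- tapply(assoc[v, ], mem, sum)
      d_c <- tapply(k, mem, sum)
      labs <- as.integer(names(w_to))
      m <- m2 / 2
      # modularity gain of moving v from community a to b
      gain <- vapply(as.character(labs), function(b) {
        if (b == a) return(0)
        (w_to[[b]] - w_to[[a]]) / m -
          k[v] * (d_c[[b]] - (d_c[[a]] - k[v])) / (2 * m^2)
      }, numeric(1))
      best <- which.max(gain)
      if (gain[best] > 1e-12) {
        mem[v] <- labs[best]
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  mem
}

#' Temporal stability of a community partition
#'
#' Splits the study into `n_periods` consecutive occasion blocks,
#' re-detects communities within each block, and reports (per block) the
#' adjusted Rand index of the block partition against the full-data
#' partition, the weighted assortativity of the full-data labels on the
#' block's network, and the block modularity; plus the pairwise ARI matrix
#' between block partitions.
#'
#' @param detections Detection tibble.
#' @param partition Full-data [detect_communities()] partition.
#' @param n_periods Number of temporal blocks (>= 1).
#' @param seed Seed forwarded to the per-block community detection.
#' @return An object of class `stability_report`: list with `blocks`
#'   (tibble) and `pairwise_ari` (matrix).
#' @export
community_stability <- function(detections, partition, n_periods, seed = 1L) {
  stopifnot(n_periods >= 1)
  d <- as_tibble(detections)
  mem_full <- partition_membership(partition)
  occ <- sort(unique(d$occasion))
  if (length(occ) < n_periods) abort("Fewer occasions than requested periods.")
  block_of <- ceiling(seq_along(occ) / (length(occ) / n_periods))
  d$block <- block_of[match(d$occasion, occ)]

  block_parts <- vector("list", n_periods)
  rows <- vector("list", n_periods)
  for (b in seq_len(n_periods)) {
    db <- d |> filter(.data$block == b, .data$id %in% mem_full$id)
    ids_b <- unique(db$id)
    if (length(ids_b) < 2L) {
      warn(sprintf("Block %d has fewer than 2 adult females; skipped.", b))
      next
    }
    gbi_b <- build_gbi(db, adult_ids = ids_b)
    sri_b <- simple_ratio_index(gbi_b)
    part_b <- tryCatch(detect_communities(sri_b, seed = seed),
                       error = function(e) NULL)
    if (is.null(part_b)) next
    block_parts[[b]] <- part_b
    common <- intersect(part_b$membership$id, mem_full$id)
    ari <- mclust::adjustedRandIndex(
      part_b$membership$community[match(common, part_b$membership$id)],
      mem_full$community[match(common, mem_full$id)]
    )
    lab_full <- mem_full$community[match(rownames(sri_b), mem_full$id)]
    rows[[b]] <- tibble(
      block = b, n_ids = length(ids_b),
      ari_vs_full = ari,
      assortativity = weighted_assortativity(sri_b, lab_full),
      modularity = part_b$modularity,
      n_communities = part_b$n_communities
    )
  }
  done <- which(!vapply(block_parts, is.null, logical(1)))
  pw <- matrix(NA_real_, n_periods, n_periods)
  for (i in done) for (j in done) {
    mi <- block_parts[[i]]$membership
    mj <- block_parts[[j]]$membership
    common <- intersect(mi$id, mj$id)
    pw[i, j] <- mclust::adjustedRandIndex(
      mi$community[match(common, mi$id)], mj$community[match(common, mj$id)]
    )
  }
  structure(
    list(blocks = list_rbind(rows[!vapply(rows, is.null, logical(1))]),
         pairwise_ari = pw, full_partition = partition),
    class = "stability_report"
  )
}

#' @export
print.stability_report <- function(x, ...) {
  cat("<stability_report>\n")
  print(x$blocks)
  invisible(x)
}

#' Weighted nominal assortativity of a labelling on a network
#'
#' Newman's assortativity coefficient for a categorical node attribute on a
#' weighted network: `r = (sum(e_ii) - sum(a_i^2)) / (1 - sum(a_i^2))`,
#' from the edge-weight mixing matrix. Randomly permuted labels give values
#' near 0; labels aligned with the weight structure approach 1.
#'
#' @param assoc Symmetric weight matrix.
#' @param labels Node labels (same order as the matrix).
#' @return Assortativity coefficient.
#' @export
weighted_assortativity <- function(assoc, labels) {
  diag(assoc) <- 0
  keep <- !is.na(labels)
  assoc <- assoc[keep, keep, drop = FALSE]
  labels <- labels[keep]
  tot <- sum(assoc)
  if (tot == 0) return(NA_real_)
  labs <- unique(labels)
  E <- matrix(0, length(labs), length(labs))
  for (i in seq_along(labs)) {
    for (j in seq_along(labs)) {
      E[i, j] <- sum(assoc[labels == labs[i], labels == labs[j]])
    }
  }
  E <- E / tot
  a <- rowSums(E)
  (sum(diag(E)) - sum(a^2)) / (1 - sum(a^2))
}
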