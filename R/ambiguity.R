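# ---- indexing-ambiguity handling ---------------------------------------
# When the rotational symmetry of the lattice exceeds the proper rotations
# of the point group (I23: lattice 432, point group 23), positions alone
# determine the orientation only up to a coset of the point group in the
# lattice group. Each indexed pattern must then be brought onto a common
# indexing convention using intensities before merging.

# proper rotations of the lattice point group: signed permutation matrices
# (det +1) that leave the reciprocal metric invariant
.lattice_rotations <- function(cell) {
  Gstar <- t(cell$B) %*% cell$B
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
                c(3, 2, 1))
  out <- list()
  for (p in perms) for (s1 in c(1, -1)) for (s2 in c(1, -1)) for (s3 in c(1, -1)) {
    M <- diag(c(s1, s2, s3))[, p, drop = FALSE]
    if (round(det(M)) != 1) next
    if (max(abs(t(M) %*% Gstar %*% M - Gstar)) < 1e-8 * max(abs(Gstar)))
      out[[length(out) + 1]] <- M
  }
  out
}

#' Indexing-ambiguity coset operators
#'
#' Representatives of the cosets of the point group's proper rotations in
#' the lattice point group, acting on (h, k, l). A single (identity)
#' operator means indexing is unambiguous for this symmetry; two or more
#' mean each still pattern's indexing must be disambiguated by intensity
#' before merging (the merohedral indexing-ambiguity problem of serial
#' crystallography).
#'
#' @param cell A [unit_cell()].
#' @param sg A [space_group()].
#' @return List of 3x3 integer matrices; first is the identity.
#' @export
ambiguity_operators <- function(cell, sg) {
  lat <- .lattice_rotations(cell)
  pg <- Filter(function(m) round(det(m)) == 1, sg$laue_ops)
  key <- function(m) paste(round(as.vector(m)), collapse = ",")
  pg_keys <- vapply(pg, key, character(1))
  reps <- list(diag(3))
  covered <- pg_keys
  for (M in lat) {
    if (key(M) %in% covered) next
    reps[[length(reps) + 1]] <- M
    covered <- c(covered, vapply(pg, function(S) key(M %*% S), character(1)))
  }
  lapply(reps, function(m) { storage.mode(m) <- "integer"; m })
}

#' Resolve the indexing ambiguity across patterns
#'
#' Reference-based disambiguation: patterns are visited in order, each
#' compared (Pearson correlation of observation intensities on shared
#' unique reflections) against the running merged reference under every
#' coset reindexing, and assigned the best-correlated alternative; a second
#' pass re-evaluates every pattern against the full reference. The first
#' pattern fixes the (arbitrary) indexing convention. Patterns with
#' insufficient overlap keep their original indexing and are flagged.
#'
#' @param obs Observation data frame (`pattern`, `h`, `k`, `l` ASU-reduced,
#'   `I`, `sigma`).
#' @param cell,sg Cell and space group.
#' @param min_common Minimum shared reflections for a decision.
#' @param n_passes Number of sweeps.
#' @return List: `obs` (reindexed), `assignment` (chosen operator per
#'   pattern), `undecided` (pattern ids).
#' @export
resolve_indexing_ambiguity <- function(obs, cell, sg, min_common = 10,
                                       n_passes = 2) {
  ops <- ambiguity_operators(cell, sg)
  pats <- unique(obs$pattern)
  if (length(ops) < 2 || length(pats) < 2)
    return(list(obs = obs, assignment = stats::setNames(rep(1L, length(pats)),
                                                        pats),
                undecided = character(0)))
  by_pat <- split(obs, obs$pattern)[pats]
  # precompute the reindexed keys of every alternative
  alts <- lapply(by_pat, function(o) {
    hkl <- as.matrix(o[, c("h", "k", "l")])
    lapply(ops, function(M) .hkl_key(asu_reduce(hkl %*% t(M), sg)))
  })
  assignment <- stats::setNames(rep(1L, length(pats)), pats)
  ref <- list(I = numeric(0), n = numeric(0), key = numeric(0))
  add_to_ref <- function(keys, I) {
    agg_i <- rowsum(I, keys)
    agg_n <- rowsum(rep(1, length(I)), keys)
    m <- match(as.numeric(rownames(agg_i)), ref$key)
    new <- is.na(m)
    if (any(!new)) ref$I[m[!new]] <<- ref$I[m[!new]] + agg_i[!new, 1]
    if (any(!new)) ref$n[m[!new]] <<- ref$n[m[!new]] + agg_n[!new, 1]
    if (any(new)) {
      ref$key <<- c(ref$key, as.numeric(rownames(agg_i))[new])
      ref$I <<- c(ref$I, agg_i[new, 1])
      ref$n <<- c(ref$n, agg_n[new, 1])
    }
  }
  undecided <- character(0)
  for (pass in seq_len(n_passes)) {
    undecided <- character(0)
    for (pi in seq_along(pats)) {
      o <- by_pat[[pi]]
      if (pass == 1 && pi == 1) {
        add_to_ref(alts[[pi]][[1]], o$I)
        next
      }
      scores <- vapply(seq_along(ops), function(ai) {
        keys <- alts[[pi]][[ai]]
        m <- match(keys, ref$key)
        ok <- !is.na(m)
        if (sum(ok) < min_common) return(NA_real_)
        suppressWarnings(stats::cor(o$I[ok], ref$I[m[ok]] / ref$n[m[ok]]))
      }, numeric(1))
      if (all(is.na(scores))) {
        undecided <- c(undecided, pats[pi])
      } else {
        assignment[pi] <- which.max(scores)
      }
      if (pass == 1) add_to_ref(alts[[pi]][[assignment[pi]]], o$I)
    }
    if (pass < n_passes) {
      # rebuild the reference from the current assignment
      ref <- list(I = numeric(0), n = numeric(0), key = numeric(0))
      for (pi in seq_along(pats))
        add_to_ref(alts[[pi]][[assignment[pi]]], by_pat[[pi]]$I)
    }
  }
  for (pi in seq_along(pats)) {
    ai <- assignment[pi]
    if (ai != 1L) {
      hkl <- as.matrix(by_pat[[pi]][, c("h", "k", "l")])
      red <- asu_reduce(hkl %*% t(ops[[ai]]), sg)
      by_pat[[pi]]$h <- red[, 1]; by_pat[[pi]]$k <- red[, 2]
      by_pat[[pi]]$l <- red[, 3]
    }
  }
  out <- do.call(rbind, by_pat)
  rownames(out) <- NULL
  list(obs = out, assignment = assignment, undecided = undecided)
}
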