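#' Pairwise distances from an alignment
#'
#' The p-distance between two aligned sequences is the mismatch fraction
#' over the columns where neither sequence has a gap. The Jukes-Cantor
#' correction \code{-3/4 log(1 - 4p/3)} is available for divergent
#' alignments; promoter homoeologs are typically close enough that the
#' raw p-distance is adequate.
#'
#' @param alignment \code{DNAStringSet}, named character vector, or
#'   character matrix of equal-length aligned sequences; \code{-} (or
#'   \code{.}) marks gaps.
#' @param model \code{"p"} (default) or \code{"JC69"}.
#' @return symmetric numeric matrix of distances (substitutions per site),
#'   zero diagonal, labelled by sequence names.
#' @export
pDistance <- function(alignment, model = c("p", "JC69")) {
  model <- match.arg(model)
  m <- alignmentMatrix(alignment)
  n <- nrow(m)
  if (n < 2) stop("need at least two sequences")
  labs <- rownames(m)
  gap <- m == "-" | m == "."
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !gap[i, ] & !gap[j, ]
      if (!any(ok))
        stop("no comparable (gap-free) columns between '", labs[i],
             "' and '", labs[j], "'")
      p <- mean(m[i, ok] != m[j, ok])
      if (model == "JC69") {
        if (p >= 0.75) stop("JC69 distance undefined at p >= 0.75")
        p <- -0.75 * log(1 - 4 * p / 3)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

alignmentMatrix <- function(alignment) {
  if (is.matrix(alignment)) {
    m <- toupper(alignment)
  } else {
    if (is(alignment, "XStringSet"))
      alignment <- stats::setNames(as.character(alignment), names(alignment))
    if (length(unique(nchar(alignment))) != 1)
      stop("aligned sequences must have equal length")
    m <- do.call(rbind, strsplit(toupper(alignment), ""))
    rownames(m) <- if (is.null(names(alignment)))
      paste0("seq", seq_along(alignment)) else names(alignment)
  }
  if (anyDuplicated(rownames(m))) stop("sequence labels must be unique")
  m
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical agglomerative neighbor joining: at each step the pair
#' minimizing the Q-criterion
#' \code{Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)} is joined,
#' with the standard branch-length formulas. Ties in Q are broken
#' deterministically by the lexicographically smallest label pair.
#' Negative branch lengths (possible on non-additive input) are clamped to
#' zero and flagged in the returned tree's \code{clamped} attribute. On an
#' additive matrix the generating tree is recovered exactly.
#'
#' @param d symmetric distance matrix with labels (>= 3 taxa).
#' @return an unrooted \code{phylo} (ape) tree with branch lengths.
#' @export
njTree <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) stop("neighbor joining needs at least 3 taxa")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", 1:n)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (any(!is.finite(d))) stop("distances must be finite")
  labs <- rownames(d)
  # each active node is represented by its newick subtree string and by a
  # sort key (smallest leaf label underneath) used for tie-breaking
  sub <- labs
  key <- labs
  clamped <- FALSE
  bl <- function(x) {
    if (x < 0) clamped <<- TRUE
    format(max(x, 0), digits = 10, scientific = FALSE, trim = TRUE)
  }
  while (nrow(d) > 3) {
    m <- nrow(d)
    r <- rowSums(d)
    Q <- (m - 2) * d - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # lexicographically smallest (sorted) label pair among the tied minima
    pairkey <- apply(cand, 1, function(ij) {
      k <- sort(c(key[ij[1]], key[ij[2]]))
      paste(k, collapse = "\r")
    })
    pick <- cand[order(pairkey)[1], ]
    i <- pick[1]; j <- pick[2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    newsub <- paste0("(", sub[i], ":", bl(li), ",", sub[j], ":", bl(lj), ")")
    newkey <- min(key[i], key[j])
    dnew <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    sub <- c(sub[keep], newsub)
    key <- c(key[keep], newkey)
    rownames(d) <- colnames(d) <- key
  }
  # final star resolution of the last three nodes
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  nwk <- paste0("(", sub[1], ":", bl(la), ",", sub[2], ":", bl(lb),
                ",", sub[3], ":", bl(lc), ");")
  tree <- ape::read.tree(text = nwk)
  attr(tree, "clamped") <- clamped
  if (clamped) warning("negative branch length(s) clamped to 0")
  tree
}

#' Neighbor-joining tree with bootstrap support
#'
#' Builds the tree from the full alignment, then resamples alignment
#' columns with replacement \code{n_reps} times, rebuilds a tree per
#' replicate, and annotates each internal edge of the base tree with the
#' percentage of replicate trees containing that bipartition. Seeded and
#' reproducible.
#'
#' @param alignment equal-length aligned sequences (see [pDistance()]).
#' @param n_reps bootstrap replicates (>= 1, default 100).
#' @param seed integer seed.
#' @param model distance model passed to [pDistance()].
#' @return a \code{phylo} tree whose \code{node.label} holds bootstrap
#'   support (%) for internal nodes.
#' @export
bootstrapTree <- function(alignment, n_reps = 100, seed = 1, model = "p") {
  if (n_reps < 1) stop("n_reps must be >= 1")
  m <- alignmentMatrix(alignment)
  base <- njTree(pDistance(m, model = model))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  reps <- vector("list", n_reps)
  for (b in seq_len(n_reps)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    # replicate trees routinely clamp on resampled columns; stay quiet
    reps[[b]] <- tryCatch(suppressWarnings(
      njTree(pDistance(m[, cols, drop = FALSE], model = model))),
      error = function(e) NULL)
  }
  reps <- Filter(Negate(is.null), reps)
  counts <- ape::prop.clades(base, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- round(100 * counts / length(reps))
  # the basal "node" of an unrooted tree is not a bipartition; no support
  support[1] <- NA
  base$node.label <- support
  base
}
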