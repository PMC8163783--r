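#' @useDynLib neuriteflow, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom Matrix sparseMatrix Diagonal rowSums colSums t solve crossprod lu
#' @importFrom stats rnorm runif setNames predict coef approx sd
#' @importFrom utils head tail read.table write.table modifyList
NULL

# Run expr with a private RNG stream, restoring the caller's .Random.seed.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Neurite morphology
#'
#' A morphology is a rooted skeleton tree of 3D sample points with radii, the
#' in-memory form of an SWC reconstruction. Positions and radii are in
#' micrometres. Exactly one point is the root (parent \code{NA}); every other
#' point references an existing parent and the parent relation is acyclic.
#'
#' @param points data.frame with columns \code{id}, \code{type}, \code{x},
#'   \code{y}, \code{z}, \code{radius}, \code{parent} (\code{NA} at the root).
#' @return An object of class \code{"morphology"} (a validated data.frame).
#' @export
morphology <- function(points) {
  cols <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(cols %in% names(points))) {
    stop("morphology points need columns: ", paste(cols, collapse = ", "))
  }
  m <- as.data.frame(points)[cols]
  m$id <- as.integer(m$id)
  m$parent <- as.integer(m$parent)
  class(m) <- c("morphology", "data.frame")
  validate_morphology(m)
  m
}

#' Validate a morphology
#'
#' Checks the structural invariants: a single root, existing parents, no
#' cycles, strictly positive radii and finite positions.
#'
#' @param m a \code{morphology}.
#' @return \code{m}, invisibly; errors on violation.
#' @export
validate_morphology <- function(m) {
  if (nrow(m) == 0L) stop("validation error: empty morphology")
  if (anyDuplicated(m$id)) stop("validation error: duplicated point ids")
  root <- is.na(m$parent) | m$parent < 0L
  if (sum(root) != 1L) {
    stop("structural error: morphology must have exactly one root, found ",
         sum(root))
  }
  known <- m$id
  bad <- !root & !(m$parent %in% known)
  if (any(bad)) {
    stop("structural error: dangling parent id(s) at point(s) ",
         paste(m$id[bad], collapse = ", "))
  }
  if (any(!root & m$parent == m$id)) {
    stop("structural error: self-parent at point(s) ",
         paste(m$id[!root & m$parent == m$id], collapse = ", "))
  }
  # cycle check: follow parents; every point must reach the root
  idx <- match(m$parent, m$id)
  n <- nrow(m)
  depth <- rep(NA_integer_, n)
  depth[which(root)] <- 0L
  for (pass in seq_len(n)) {
    todo <- which(is.na(depth))
    if (!length(todo)) break
    pd <- depth[idx[todo]]
    depth[todo[!is.na(pd)]] <- pd[!is.na(pd)] + 1L
  }
  if (anyNA(depth)) {
    stop("structural error: cycle detected involving point(s) ",
         paste(m$id[is.na(depth)], collapse = ", "))
  }
  if (any(!is.finite(m$x) | !is.finite(m$y) | !is.finite(m$z))) {
    stop("validation error: non-finite positions")
  }
  if (any(!is.finite(m$radius) | m$radius <= 0)) {
    stop("validation error: radii must be strictly positive")
  }
  invisible(m)
}

#' Read an SWC morphology file
#'
#' Parses the NeuroMorpho SWC dialect: '#' comment lines, then 7
#' whitespace-separated columns (id, type, x, y, z, radius, parent), parent -1
#' at the root. Unknown type codes are accepted and preserved.
#'
#' @param path path to an SWC text file.
#' @return a \code{morphology}.
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  recs <- lines[keep]
  lineno <- seq_along(lines)[keep]
  if (!length(recs)) stop("validation error: empty morphology (no records in ", path, ")")
  fields <- strsplit(trimws(recs), "\\s+")
  nf <- lengths(fields)
  if (any(nf != 7L)) {
    stop("parse error at line ", lineno[which(nf != 7L)[1L]],
         ": expected 7 fields, got ", nf[which(nf != 7L)[1L]])
  }
  vals <- suppressWarnings(matrix(as.numeric(unlist(fields)), ncol = 7, byrow = TRUE))
  if (anyNA(vals)) {
    stop("parse error at line ", lineno[which(rowSums(is.na(vals)) > 0)[1L]],
         ": non-numeric field")
  }
  parent <- as.integer(vals[, 7])
  parent[parent < 0L] <- NA_integer_
  morphology(data.frame(
    id = as.integer(vals[, 1]), type = as.integer(vals[, 2]),
    x = vals[, 3], y = vals[, 4], z = vals[, 5],
    radius = vals[, 6], parent = parent
  ))
}

#' Write a morphology to SWC
#'
#' @param m a \code{morphology}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_swc <- function(m, path) {
  validate_morphology(m)
  p <- m$parent
  p[is.na(p)] <- -1L
  lines <- sprintf("%d %d %.9g %.9g %.9g %.9g %d",
                   m$id, m$type, m$x, m$y, m$z, m$radius, p)
  writeLines(c("# SWC written by neuriteflow", lines), path)
  invisible(path)
}

#' Serialize / restore a morphology as JSON
#'
#' Plain-text fixture format: one object with parallel arrays per column.
#'
#' @param m a \code{morphology}.
#' @param path output (input) file path.
#' @return \code{path} invisibly (or the \code{morphology} for the reader).
#' @export
write_morphology_json <- function(m, path) {
  validate_morphology(m)
  jsonlite::write_json(as.list(as.data.frame(m)), path, auto_unbox = FALSE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_morphology_json
#' @export
read_morphology_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$parent <- as.integer(x$parent)
  morphology(as.data.frame(x))
}

# Rodrigues rotation of v about unit axis a by angle th
rotate_about <- function(v, a, th) {
  v * cos(th) + pracma_cross(a, v) * sin(th) + a * sum(a * v) * (1 - cos(th))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

unitize <- function(v) v / sqrt(sum(v^2))

# any unit vector orthogonal to d
orth_to <- function(d) {
  ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unitize(pracma_cross(d, ref))
}

#' Generate a synthetic branched morphology
#'
#' Grows a rooted binary tree with the requested number of bifurcations.
#' Branch radii taper geometrically with branch order; skeleton points are
#' laid down at \code{sampling_spacing} along gently curved branch
#' centerlines. Deterministic for a given \code{seed}.
#'
#' @param n_bifurcations number of degree-3 branch points (>= 0).
#' @param branch_length_range (min, max) branch length in micrometres.
#' @param radius_root radius of the root branch, micrometres.
#' @param taper_ratio radius multiplier per branch order, in (0, 1].
#' @param sampling_spacing skeleton sampling step, micrometres.
#' @param seed integer seed.
#' @param branch_angle_range polar angle range (degrees) between a child
#'   branch and its parent direction.
#' @param curvature magnitude of the random per-branch direction drift, in
#'   radians per micrometre of arc length.
#' @return a \code{morphology}.
#' @export
generate_morphology <- function(n_bifurcations = 2,
                                branch_length_range = c(12, 20),
                                radius_root = 1.0,
                                taper_ratio = 0.85,
                                sampling_spacing = 1.0,
                                seed = 1,
                                branch_angle_range = c(20, 40),
                                curvature = 0.02) {
  stopifnot(n_bifurcations >= 0, radius_root > 0, sampling_spacing > 0,
            taper_ratio > 0, taper_ratio <= 1,
            branch_length_range[1] <= branch_length_range[2])
  if (sampling_spacing > branch_length_range[2]) {
    stop("configuration error: sampling_spacing exceeds the maximum branch length")
  }
  with_seed(seed, {
    # topology: split random leaves until n_bifurcations reached
    parent_branch <- c(NA_integer_)
    order <- c(0L)
    leaves <- 1L
    for (b in seq_len(n_bifurcations)) {
      pick <- if (length(leaves) == 1L) leaves else leaves[sample.int(length(leaves), 1L)]
      nb <- length(parent_branch)
      parent_branch <- c(parent_branch, pick, pick)
      order <- c(order, order[pick] + 1L, order[pick] + 1L)
      leaves <- c(setdiff(leaves, pick), nb + 1L, nb + 2L)
    }
    nb <- length(parent_branch)
    # geometry, branches created parents-first
    end_point <- vector("list", nb)
    end_dir <- vector("list", nb)
    end_id <- integer(nb)
    child_count <- integer(nb)
    pts <- list()
    next_id <- 1L
    for (bi in seq_len(nb)) {
      if (is.na(parent_branch[bi])) {
        start <- c(0, 0, 0)
        d <- unitize(c(rnorm(2, 0, 0.1), 1))
        start_parent <- NA_integer_
      } else {
        pb <- parent_branch[bi]
        start <- end_point[[pb]]
        pd <- end_dir[[pb]]
        child_count[pb] <- child_count[pb] + 1L
        th <- runif(1, branch_angle_range[1], branch_angle_range[2]) * pi / 180
        if (child_count[pb] == 1L) {
          phi <- runif(1, 0, 2 * pi)
          attr(end_dir[[pb]], "phi") <- phi
        } else {
          phi <- attr(end_dir[[pb]], "phi") + pi + runif(1, -0.4, 0.4)
        }
        u <- orth_to(pd); w <- pracma_cross(pd, u)
        d <- unitize(cos(th) * pd + sin(th) * (cos(phi) * u + sin(phi) * w))
        start_parent <- end_id[pb]
      }
      len <- runif(1, branch_length_range[1], branch_length_range[2])
      npt <- max(2L, ceiling(len / sampling_spacing) + 1L)
      step <- len / (npt - 1)
      r <- radius_root * taper_ratio^order[bi]
      drift <- rnorm(3) * curvature
      p <- start
      prev <- start_parent
      for (k in 2:npt) {
        d <- unitize(d + step * (drift - sum(drift * d) * d))
        p <- p + step * d
        pts[[length(pts) + 1L]] <- c(next_id, p, r, prev)
        prev <- next_id
        next_id <- next_id + 1L
      }
      if (is.na(parent_branch[bi])) {
        # emit the root point first (prepend)
        root_rec <- c(next_id, start, r, NA)
        pts <- c(list(root_rec), pts)
        # re-point the first emitted point of this branch to the root id
        pts[[2L]][6L] <- next_id
        root_id <- next_id
        next_id <- next_id + 1L
      }
      end_point[[bi]] <- p
      end_dir[[bi]] <- d
      end_id[bi] <- prev
    }
    mat <- do.call(rbind, pts)
    df <- data.frame(id = mat[, 1], type = 3L, x = mat[, 2], y = mat[, 3],
                     z = mat[, 4], radius = mat[, 5], parent = mat[, 6])
    # renumber so ids are 1..n in parent-before-child order
    ord <- order(is.na(df$parent), decreasing = TRUE)
    df <- df[ord, ]
    remap <- setNames(seq_len(nrow(df)), df$id)
    df$id <- as.integer(remap[as.character(df$id)])
    df$parent <- ifelse(is.na(df$parent), NA_integer_,
                        as.integer(remap[as.character(df$parent)]))
    rownames(df) <- NULL
    df$type[1] <- 1L
    morphology(df)
  })
}

#' @export
print.morphology <- function(x, ...) {
  root <- which(is.na(x$parent))
  kids <- table(factor(x$parent, levels = x$id))
  cat("Neurite morphology: ", nrow(x), " points, ",
      sum(kids >= 2L), " branch point(s), ", sum(kids == 0L), " tip(s)\n", sep = "")
  cat("  root id ", x$id[root], "; radius range [",
      format(min(x$radius), digits = 3), ", ",
      format(max(x$radius), digits = 3), "] um\n", sep = "")
  invisible(x)
}
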