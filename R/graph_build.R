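# Cross-section node templates and neurite decomposition.
#
# A morphology is decomposed into bifurcation units (one per degree-3 branch
# point: the branch-point cross section plus 3 cross sections along each
# incident branch) and pipe units (the remaining runs of cross sections).
# Every cross section carries a fixed node template: 17 nodes (1 center, 8 at
# r = R/2, 8 at r = R) on ordinary sections, 23 (6 extra wall nodes near the
# three branch-junction azimuths) on the branch-point section. Units sharing
# a section are joined by an interface.

TPL_DELTA <- pi / 16  # angular offset of the paired extra wall nodes
TPL_MIN_SEP <- pi / 16  # minimum angular separation on the outer ring

# nudge the extra wall nodes so all outer-ring nodes keep a minimum angular
# separation (junction azimuths can fall arbitrarily close to the 8 fixed
# ring angles, which would otherwise create near-zero edge lengths)
spread_extras <- function(ext, base, dmin = TPL_MIN_SEP) {
  # canonical (sorted-angle) processing order so the result depends only on
  # the set of requested azimuths, not on branch enumeration order
  ext <- sort(ext %% (2 * pi))
  for (it in 1:10) {
    moved <- FALSE
    for (k in seq_along(ext)) {
      others <- c(base, ext[-k])
      dd <- atan2(sin(ext[k] - others), cos(ext[k] - others))
      cl <- which.min(abs(dd))
      if (abs(dd[cl]) < dmin * 0.999) {
        sgn <- if (dd[cl] == 0) 1 else sign(dd[cl])
        ext[k] <- others[cl] + sgn * dmin
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  ext
}

# local polar layout of a section template; jang: junction azimuths (23 only)
template_offsets <- function(nn, jang = NULL) {
  ang8 <- (0:7) * pi / 4
  a <- c(0, ang8, ang8)
  rr <- c(0, rep(0.5, 8), rep(1, 8))
  if (nn == 23L) {
    stopifnot(length(jang) == 3L)
    ext <- spread_extras(rep(jang, each = 2) + c(-TPL_DELTA, TPL_DELTA), ang8)
    a <- c(a, ext)
    rr <- c(rr, rep(1, 6))
  }
  list(a = a, rr = rr)
}

# within-section edges in template-index space
template_edges <- function(nn, jang = NULL) {
  spokes <- cbind(1L, 2:9)
  inner <- cbind(2:9, c(3:9, 2L))
  radial <- cbind(2:9, 10:17)
  off <- template_offsets(nn, jang)
  outer_ti <- which(off$rr == 1)
  ord <- outer_ti[order(off$a[outer_ti] %% (2 * pi))]
  ring <- cbind(ord, c(ord[-1], ord[1]))
  rbind(spokes, inner, radial, ring)
}

transport_frame <- function(e1, t_new) {
  v <- e1 - sum(e1 * t_new) * t_new
  n <- sqrt(sum(v^2))
  if (n < 1e-8) v <- orth_to(t_new) else v <- v / n
  v
}

empty_sections <- function(n = 0L) {
  data.frame(cx = numeric(n), cy = numeric(n), cz = numeric(n),
             radius = numeric(n),
             tx = numeric(n), ty = numeric(n), tz = numeric(n),
             e1x = numeric(n), e1y = numeric(n), e1z = numeric(n),
             nn = integer(n), parent = integer(n),
             ja1 = numeric(n), ja2 = numeric(n), ja3 = numeric(n),
             u_rel = numeric(n), seg = integer(n))
}

section_row <- function(center, radius, t, e1, nn = 17L, jang = c(NA, NA, NA),
                        parent = 0L, seg = 0L) {
  data.frame(cx = center[1], cy = center[2], cz = center[3], radius = radius,
             tx = t[1], ty = t[2], tz = t[3],
             e1x = e1[1], e1y = e1[2], e1z = e1[3],
             nn = as.integer(nn), parent = as.integer(parent),
             ja1 = jang[1], ja2 = jang[2], ja3 = jang[3],
             u_rel = NA_real_, seg = as.integer(seg))
}

# Area-weighted flux conservation along the section tree: mean axial speed
# scales with R_parent^2 / R^2 along a run, and a parent's volumetric flux is
# split over its children in proportion to their cross-section areas.
fill_u_rel <- function(sections) {
  n <- nrow(sections)
  kids <- split(seq_len(n), factor(sections$parent, levels = 0:n))
  u <- rep(NA_real_, n)
  queue <- kids[["0"]]
  u[queue] <- 1
  while (length(queue)) {
    s <- queue[[1]]; queue <- queue[-1]
    ch <- kids[[as.character(s)]]
    if (length(ch)) {
      if (length(ch) == 1L) {
        u[ch] <- u[s] * (sections$radius[s] / sections$radius[ch])^2
      } else {
        u[ch] <- u[s] * sections$radius[s]^2 / sum(sections$radius[ch]^2)
      }
      queue <- c(queue, ch)
    }
  }
  sections$u_rel <- u
  sections
}

# Instantiate the node-level graph for a set of sections linked by `parent`.
# sec_role: "interior" / "inlet" / "outlet" per section; sec_iface: interface
# id or NA.
build_graph_from_sections <- function(sections, sec_role, sec_iface, kind) {
  ns <- nrow(sections)
  stopifnot(length(sec_role) == ns, length(sec_iface) == ns)
  if (anyNA(sections$u_rel)) sections <- fill_u_rel(sections)
  nn <- sections$nn
  offset <- c(0L, cumsum(nn))
  N <- offset[ns + 1L]
  pos <- matrix(0, N, 3)
  r_frac <- numeric(N)
  ti <- integer(N)
  sec <- integer(N)
  edges <- vector("list", 2L * ns)
  for (s in seq_len(ns)) {
    off <- template_offsets(nn[s], unlist(sections[s, c("ja1", "ja2", "ja3")]))
    t <- unlist(sections[s, c("tx", "ty", "tz")])
    e1 <- unlist(sections[s, c("e1x", "e1y", "e1z")])
    e2 <- pracma_cross(t, e1)
    ctr <- unlist(sections[s, c("cx", "cy", "cz")])
    R <- sections$radius[s]
    idx <- offset[s] + seq_len(nn[s])
    pos[idx, ] <- rep(ctr, each = nn[s]) +
      R * off$rr * (cos(off$a) %o% e1 + sin(off$a) %o% e2)
    r_frac[idx] <- off$rr
    ti[idx] <- seq_len(nn[s])
    sec[idx] <- s
    edges[[2L * s - 1L]] <- offset[s] + template_edges(nn[s], unlist(sections[s, c("ja1", "ja2", "ja3")]))
    p <- sections$parent[s]
    if (p > 0L) {
      edges[[2L * s]] <- cbind(offset[p] + 1:17, offset[s] + 1:17)
    }
  }
  edges <- do.call(rbind, edges)
  storage.mode(edges) <- "integer"
  role <- sec_role[sec]
  iface <- sec_iface[sec]
  g <- list(pos = pos, radius = sections$radius[sec], sec = sec, ti = ti,
            r_frac = r_frac, role = role, iface = iface, edges = edges,
            sections = sections, sec_role = sec_role, sec_iface = sec_iface,
            kind = kind, n = N)
  class(g) <- "template_graph"
  g
}

#' @export
print.template_graph <- function(x, ...) {
  cat("Template graph (", x$kind, "): ", x$n, " nodes, ",
      nrow(x$edges), " edges, ", nrow(x$sections), " cross sections\n", sep = "")
  cat("  roles:", paste(sprintf("%s=%d", names(table(x$role)), table(x$role)),
                        collapse = ", "), "\n")
  invisible(x)
}

#' Pipe unit
#'
#' An unbranched run of neurite with a centerline and per-point radii.
#'
#' @param centerline k x 3 matrix of centerline points (micrometres), ordered
#'   from the inlet end.
#' @param radii per-point radii (micrometres) or a single value.
#' @param u_in mean axial speed at the unit inlet relative to the network
#'   inlet speed (1 for a standalone pipe).
#' @return an object of class \code{"pipe_unit"}.
#' @export
pipe_unit <- function(centerline, radii, u_in = 1) {
  centerline <- as.matrix(centerline)
  stopifnot(ncol(centerline) == 3, nrow(centerline) >= 2)
  radii <- rep_len(radii, nrow(centerline))
  stopifnot(all(radii > 0))
  d <- sqrt(rowSums((centerline[-1, , drop = FALSE] -
                     centerline[-nrow(centerline), , drop = FALSE])^2))
  if (any(d <= 0)) stop("centerline must have a monotone arc-length parameterization")
  structure(list(centerline = centerline, radii = radii, u_in = u_in,
                 sections = NULL, sec_role = NULL, sec_iface = NULL),
            class = "pipe_unit")
}

#' Bifurcation unit
#'
#' A degree-3 branch point plus three branch stubs, each described by 3
#' cross-section centers (ordered outward from the branch point) and radii.
#' Branch 1 is the parent (inlet-side) branch.
#'
#' @param branch_point 3-vector, micrometres.
#' @param branches list of 3 lists, each with \code{centers} (3 x 3 matrix)
#'   and \code{radii} (length 3).
#' @param radius radius of the branch-point cross section; defaults to the
#'   innermost parent-stub radius.
#' @param u_in as in \code{\link{pipe_unit}}.
#' @return an object of class \code{"bifurcation_unit"}.
#' @export
bifurcation_unit <- function(branch_point, branches, radius = NULL, u_in = 1) {
  stopifnot(length(branches) == 3L)
  for (b in branches) {
    stopifnot(nrow(as.matrix(b$centers)) == 3L, length(b$radii) == 3L,
              all(b$radii > 0))
  }
  if (is.null(radius)) radius <- branches[[1]]$radii[1]
  structure(list(branch_point = as.numeric(branch_point), branches = branches,
                 radius = radius, u_in = u_in,
                 sections = NULL, sec_role = NULL, sec_iface = NULL),
            class = "bifurcation_unit")
}

polyline_length <- function(pts) {
  sum(sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2)))
}

# interpolate a polyline (k x 3, radii k) at arc positions s
interp_polyline <- function(pts, radii, s) {
  seglen <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  arc <- c(0, cumsum(seglen))
  s <- pmin(pmax(s, 0), arc[length(arc)])
  ctr <- cbind(approx(arc, pts[, 1], s)$y, approx(arc, pts[, 2], s)$y,
               approx(arc, pts[, 3], s)$y)
  rad <- approx(arc, radii, s)$y
  # tangent: direction of the polyline piece containing each s
  piece <- pmin(findInterval(s, arc, rightmost.closed = TRUE), length(seglen))
  piece <- pmax(piece, 1L)
  tans <- (pts[piece + 1L, , drop = FALSE] - pts[piece, , drop = FALSE]) / seglen[piece]
  list(center = ctr, radius = rad, tangent = tans, length = arc[length(arc)])
}

# sections j = 0..n along a polyline, frames parallel-transported from frame0;
# returns the full table (caller subsets) plus the end frame
walk_sections <- function(pts, radii, n, frame0, seg = 0L) {
  ip <- interp_polyline(pts, radii, seq(0, 1, length.out = n + 1L) *
                          polyline_length(pts))
  e1 <- frame0$e1
  rows <- vector("list", n + 1L)
  for (j in 0:n) {
    t <- unitize(ip$tangent[j + 1L, ])
    e1 <- transport_frame(e1, t)
    rows[[j + 1L]] <- section_row(ip$center[j + 1L, ], ip$radius[j + 1L], t, e1,
                                  seg = seg)
  }
  list(sections = do.call(rbind, rows),
       end_frame = list(t = unitize(ip$tangent[n + 1L, ]), e1 = e1))
}

#' Build the template graph of a pipe unit
#'
#' Places \code{max(2, ceiling(length / spacing) + 1)} cross sections along
#' the centerline (or reuses sections precomputed by
#' \code{\link{decompose_morphology}}), each carrying the fixed 17-node
#' template scaled to the local radius and oriented normal to the local
#' tangent by parallel transport.
#'
#' @param p a \code{pipe_unit}.
#' @param section_spacing target spacing between cross sections, micrometres;
#'   default twice the mean radius.
#' @return a \code{template_graph}.
#' @export
build_pipe_graph <- function(p, section_spacing = NULL) {
  stopifnot(inherits(p, "pipe_unit"))
  if (!is.null(p$sections)) {
    return(build_graph_from_sections(p$sections, p$sec_role, p$sec_iface, "pipe"))
  }
  len <- polyline_length(p$centerline)
  if (len <= 0) stop("zero-length pipe")
  if (is.null(section_spacing)) section_spacing <- 2 * mean(p$radii)
  if (len < section_spacing) section_spacing <- len
  n <- max(1L, as.integer(ceiling(len / section_spacing)))
  t0 <- unitize(p$centerline[2, ] - p$centerline[1, ])
  ws <- walk_sections(p$centerline, p$radii, n, list(e1 = orth_to(t0)))
  sections <- ws$sections
  ns <- nrow(sections)
  sections$parent <- c(0L, seq_len(ns - 1L))
  sections$u_rel <- p$u_in * (sections$radius[1] / sections$radius)^2
  role <- c("inlet", rep("interior", ns - 2L), "outlet")
  build_graph_from_sections(sections, role, rep(NA_integer_, ns), "pipe")
}

#' Build the template graph of a bifurcation unit
#'
#' The branch-point cross section carries the 23-node template (the 17-node
#' template plus 6 extra wall nodes flanking the three branch-junction
#' azimuths); each of the three branch stubs carries 3 ordinary 17-node
#' sections, giving 23 + 9 x 17 = 176 nodes.
#'
#' @param b a \code{bifurcation_unit}.
#' @return a \code{template_graph}.
#' @export
build_bifurcation_graph <- function(b) {
  stopifnot(inherits(b, "bifurcation_unit"))
  if (!is.null(b$sections)) {
    return(build_graph_from_sections(b$sections, b$sec_role, b$sec_iface,
                                     "bifurcation"))
  }
  bp <- b$branch_point
  par <- b$branches[[1]]
  parc <- as.matrix(par$centers)
  # parent stub walked inward: outermost section -> branch point
  ppoly <- rbind(parc[3:1, , drop = FALSE], bp)
  prad <- c(par$radii[3:1], b$radius)
  t0 <- unitize(ppoly[2, ] - ppoly[1, ])
  ws <- walk_parent_stub(ppoly, prad, list(e1 = orth_to(t0)))
  psec <- ws$sections           # rows: 3 parent sections then the bp section
  frame_bp <- ws$end_frame
  # child stubs: frames transported from the branch point
  proj_angle <- function(d, fr) {
    e2 <- pracma_cross(fr$t, fr$e1)
    v <- c(sum(d * fr$e1), sum(d * e2))
    if (sqrt(sum(v^2)) < 1e-8) return(NA_real_)
    atan2(v[2], v[1])
  }
  cdir <- lapply(2:3, function(k) {
    unitize(as.matrix(b$branches[[k]]$centers)[1, ] - bp)
  })
  a1 <- proj_angle(cdir[[1]], frame_bp)
  a2 <- proj_angle(cdir[[2]], frame_bp)
  if (is.na(a1)) a1 <- 0
  if (is.na(a2)) a2 <- a1 + 2 * pi / 3
  vsum <- c(cos(a1) + cos(a2), sin(a1) + sin(a2))
  # degenerate (opposed children): pick the fallback from the smaller
  # normalized azimuth so the convention is invariant under child swapping
  a3 <- if (sqrt(sum(vsum^2)) < 1e-8) {
    min(a1 %% (2 * pi), a2 %% (2 * pi)) + pi
  } else atan2(-vsum[2], -vsum[1])
  psec$nn[4L] <- 23L
  psec[4L, c("ja1", "ja2", "ja3")] <- c(a1, a2, a3)
  secs <- psec
  roles <- c("inlet", rep("interior", 3L))
  for (k in 2:3) {
    br <- b$branches[[k]]
    cpoly <- rbind(bp, as.matrix(br$centers))
    crad <- c(b$radius, br$radii)
    tk <- cdir[[k - 1L]]
    e1k <- transport_frame(frame_bp$e1, tk)
    wk <- walk_sections(cpoly, crad, 3L, list(e1 = e1k))
    ck <- wk$sections[-1L, , drop = FALSE]  # drop the bp-position row
    ck$parent <- c(4L, nrow(secs) + 1L, nrow(secs) + 2L)
    secs <- rbind(secs, ck)
    roles <- c(roles, "interior", "interior", "outlet")
  }
  secs$u_rel <- NA_real_
  secs <- fill_u_rel(secs)
  secs$u_rel <- secs$u_rel * b$u_in
  build_graph_from_sections(secs, roles, rep(NA_integer_, nrow(secs)),
                            "bifurcation")
}

# parent stub: sections at the 3 given centers plus the branch point
walk_parent_stub <- function(ppoly, prad, frame0) {
  e1 <- frame0$e1
  rows <- vector("list", 4L)
  for (j in 1:4) {
    t <- if (j < 4L) unitize(ppoly[j + 1L, ] - ppoly[j, ]) else
      unitize(ppoly[4L, ] - ppoly[3L, ])
    e1 <- transport_frame(e1, t)
    rows[[j]] <- section_row(ppoly[j, ], prad[j], t, e1,
                             parent = j - 1L)
  }
  list(sections = do.call(rbind, rows),
       end_frame = list(t = unitize(ppoly[4L, ] - ppoly[3L, ]), e1 = e1))
}
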