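# Decomposition of a morphology into pipe and bifurcation units.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Degree>3 skeleton branch points are split into cascaded degree-3
# bifurcations: extra children are re-parented onto a new point nudged a
# fraction of the local radius toward the first extra child.
split_polytomies <- function(m) {
  repeat {
    kids <- table(factor(m$parent, levels = m$id))
    over <- names(kids)[kids > 2L]
    if (!length(over)) return(m)
    pid <- as.integer(over[1L])
    prow <- which(m$id == pid)
    ch <- which(!is.na(m$parent) & m$parent == pid)
    extra <- ch[-(1:2)]
    dir <- unitize(unlist(m[extra[1L], c("x", "y", "z")]) -
                     unlist(m[prow, c("x", "y", "z")]))
    newid <- max(m$id) + 1L
    newpt <- m[prow, ]
    newpt$id <- newid
    newpt[, c("x", "y", "z")] <- m[prow, c("x", "y", "z")] +
      0.5 * m$radius[prow] * dir
    newpt$parent <- pid
    m$parent[extra] <- newid
    m <- rbind(m, newpt)
    class(m) <- c("morphology", "data.frame")
  }
}

#' Decompose a morphology into pipe and bifurcation units
#'
#' Cross sections are placed along every branch at roughly
#' \code{section_spacing} (default twice the local mean radius). Each degree-3
#' branch point becomes a bifurcation unit claiming the 23-node branch-point
#' section plus the 3 nearest sections along each incident branch; the
#' remaining section runs become pipe units. Units sharing a section are
#' linked by an interface; long pipes can be split into chunks (yielding
#' pipe-pipe interfaces) via \code{max_pipe_sections}. Very short internal
#' branches whose two bifurcations meet directly yield a
#' bifurcation-bifurcation interface.
#'
#' @param m a \code{morphology}.
#' @param section_spacing target cross-section spacing, micrometres;
#'   \code{NULL} for twice the local mean radius.
#' @param max_pipe_sections split pipe units longer than this many sections
#'   (default \code{Inf}: never split).
#' @return an object of class \code{"structure_graph"}.
#' @export
decompose_morphology <- function(m, section_spacing = NULL,
                                 max_pipe_sections = Inf) {
  validate_morphology(m)
  m <- split_polytomies(m)
  n <- nrow(m)
  idx <- match(m$parent, m$id)
  children <- lapply(seq_len(n), function(i) which(idx == i))
  nchild <- lengths(children)
  root <- which(is.na(idx))
  is_bp <- nchild >= 2L
  if (is_bp[root]) {
    stop("decomposition error: the root must not itself be a branch point")
  }

  # topology: segments between terminals (root, tips, branch points)
  segs <- list()
  terms <- root
  seen <- logical(n)
  while (length(terms)) {
    t0 <- terms[[1L]]; terms <- terms[-1L]
    for (c0 in children[[t0]]) {
      path <- c(t0, c0)
      cur <- c0
      while (nchild[cur] == 1L && !is_bp[cur]) {
        cur <- children[[cur]][1L]
        path <- c(path, cur)
      }
      segs[[length(segs) + 1L]] <- list(rows = path, A = t0, B = cur,
                                        Abp = is_bp[t0] && t0 != root,
                                        Bbp = is_bp[cur])
      if (is_bp[cur] && !seen[cur]) { terms <- c(terms, cur); seen[cur] <- TRUE }
    }
  }
  seg_A <- vapply(segs, `[[`, 0L, "A")

  # geometric pass in BFS order (parents of a branch point before children)
  sec_tab <- NULL
  seg_info <- vector("list", length(segs))
  bp_secid <- integer(n); bp_frame <- vector("list", n); bp_inseg <- integer(n)
  seg_t0 <- vector("list", length(segs))
  add_rows <- function(rows) {
    sec_tab <<- rbind(sec_tab, rows)
    nrow(sec_tab) - nrow(rows) + seq_len(nrow(rows))
  }
  order_q <- root
  done_term <- logical(n)
  while (length(order_q)) {
    t0 <- order_q[[1L]]; order_q <- order_q[-1L]
    if (done_term[t0]) next
    done_term[t0] <- TRUE
    if (is_bp[t0] && bp_secid[t0] == 0L && t0 != root) next  # not reached yet
    for (si in which(seg_A == t0)) {
      sg <- segs[[si]]
      pts <- as.matrix(m[sg$rows, c("x", "y", "z")])
      radii <- m$radius[sg$rows]
      L <- polyline_length(pts)
      h_t <- section_spacing %||% (2 * mean(radii))
      min_n <- if (sg$Abp && sg$Bbp) 6L else if (sg$Abp || sg$Bbp) 4L else 1L
      nsec <- max(as.integer(ceiling(L / h_t)), min_n)
      h <- L / nsec
      if (h < 0.4 * mean(radii)) {
        stop("decomposition error: segment near (",
             paste(round(pts[1, ], 2), collapse = ", "),
             ") too short (", round(L, 2), " um) to host its units")
      }
      t00 <- unitize(pts[2L, ] - pts[1L, ])
      seg_t0[[si]] <- t00
      e10 <- if (sg$Abp) transport_frame(bp_frame[[t0]]$e1, t00) else orth_to(t00)
      ws <- walk_sections(pts, radii, nsec, list(e1 = e10), seg = si)
      full <- ws$sections
      gid <- integer(nsec + 1L)
      incl <- setdiff(0:nsec, c(if (sg$Abp) 0L, if (sg$Bbp) nsec))
      new_ids <- add_rows(full[incl + 1L, , drop = FALSE])
      gid[incl + 1L] <- new_ids
      if (sg$Abp) gid[1L] <- bp_secid[t0]
      # parent pointers toward the root
      for (j in incl) {
        sec_tab$parent[gid[j + 1L]] <- if (j == 0L) 0L else gid[j]
      }
      if (sg$Bbp) {
        bprow <- full[nsec + 1L, , drop = FALSE]
        bprow$nn <- 23L
        bprow$parent <- gid[nsec]
        bid <- add_rows(bprow)
        gid[nsec + 1L] <- bid
        bp_secid[sg$B] <- bid
        bp_frame[[sg$B]] <- list(
          t = unlist(bprow[1, c("tx", "ty", "tz")]),
          e1 = unlist(bprow[1, c("e1x", "e1y", "e1z")]))
        bp_inseg[sg$B] <- si
        order_q <- c(order_q, sg$B)
      }
      seg_info[[si]] <- list(gid = gid, n = nsec)
    }
  }

  # branch-junction azimuths for the 23-node sections
  for (t0 in which(is_bp)) {
    fr <- bp_frame[[t0]]
    e2 <- pracma_cross(fr$t, fr$e1)
    csegs <- which(seg_A == t0)
    ang <- vapply(csegs[1:2], function(si) {
      d <- seg_t0[[si]]
      v <- c(sum(d * fr$e1), sum(d * e2))
      if (sqrt(sum(v^2)) < 1e-8) NA_real_ else atan2(v[2], v[1])
    }, 0)
    if (is.na(ang[1])) ang[1] <- 0
    if (is.na(ang[2])) ang[2] <- ang[1] + 2 * pi / 3
    vs <- c(cos(ang[1]) + cos(ang[2]), sin(ang[1]) + sin(ang[2]))
    a3 <- if (sqrt(sum(vs^2)) < 1e-8) {
      min(ang[1] %% (2 * pi), ang[2] %% (2 * pi)) + pi
    } else atan2(-vs[2], -vs[1])
    sec_tab[bp_secid[t0], c("ja1", "ja2", "ja3")] <- c(ang[1], ang[2], a3)
  }

  sec_tab$u_rel <- NA_real_
  sec_tab <- fill_u_rel(sec_tab)

  # units
  units <- list()
  iface_sections <- integer(0)   # global section id per interface
  iface_units <- list()          # pending unit labels per interface
  bif_of_term <- integer(n)
  for (t0 in which(is_bp)) {
    insi <- bp_inseg[t0]
    gin <- seg_info[[insi]]$gid; nin <- seg_info[[insi]]$n
    pside <- gin[(nin - 3L):(nin - 1L) + 1L]
    gids <- c(pside, bp_secid[t0])
    for (si in which(seg_A == t0)) gids <- c(gids, seg_info[[si]]$gid[2:4])
    uid <- length(units) + 1L
    units[[uid]] <- list(kind = "bifurcation", sections_global = gids)
    bif_of_term[t0] <- uid
  }
  add_iface <- function(sec_gid, ua, ub) {
    iface_sections <<- c(iface_sections, sec_gid)
    iface_units[[length(iface_sections)]] <<- c(ua, ub)
  }
  for (si in seq_along(segs)) {
    sg <- segs[[si]]
    gid <- seg_info[[si]]$gid; nsec <- seg_info[[si]]$n
    a <- if (sg$Abp) 3L else 0L
    b <- if (sg$Bbp) nsec - 3L else nsec
    if (b - a >= 1L) {
      len <- b - a + 1L
      k <- if (is.finite(max_pipe_sections) && len > max_pipe_sections) {
        as.integer(ceiling((len - 1) / (max_pipe_sections - 1)))
      } else 1L
      bnd <- a + as.integer(round(seq(0L, b - a, length.out = k + 1L)))
      first_uid <- length(units) + 1L
      for (ci in seq_len(k)) {
        gids <- gid[(bnd[ci]:bnd[ci + 1L]) + 1L]
        units[[length(units) + 1L]] <- list(kind = "pipe", sections_global = gids)
        if (ci > 1L) add_iface(gid[bnd[ci] + 1L], length(units) - 1L, length(units))
      }
      if (sg$Abp) add_iface(gid[a + 1L], bif_of_term[sg$A], first_uid)
      if (sg$Bbp) add_iface(gid[b + 1L], length(units), bif_of_term[sg$B])
    } else if (sg$Abp && sg$Bbp && a == b) {
      add_iface(gid[a + 1L], bif_of_term[sg$A], bif_of_term[sg$B])
    } else {
      stop("decomposition error: segment ", si, " cannot host its units")
    }
  }

  # per-unit interface labels
  iface_of_sec <- rep(NA_integer_, nrow(sec_tab))
  iface_of_sec[iface_sections] <- seq_along(iface_sections)
  kinds <- vapply(units, `[[`, "", "kind")
  iface_kind <- vapply(seq_along(iface_sections), function(i) {
    kk <- sort(substr(kinds[iface_units[[i]]], 1, 1), decreasing = TRUE)
    paste(kk, collapse = "-")  # "p-p", "p-b" or "b-b"
  }, "")

  units <- lapply(seq_along(units), function(ui) {
    u <- units[[ui]]
    gids <- u$sections_global
    secs <- sec_tab[gids, , drop = FALSE]
    rownames(secs) <- NULL
    lp <- match(sec_tab$parent[gids], gids)
    secs$parent <- ifelse(is.na(lp), 0L, lp)
    haschild <- seq_along(gids) %in% secs$parent
    sec_role <- ifelse(secs$parent == 0L, "inlet",
                       ifelse(!haschild, "outlet", "interior"))
    # a true network inlet only at the morphology root section
    obj <- structure(list(kind = u$kind, id = ui,
                          sections = secs,
                          sec_role = sec_role,
                          sec_iface = iface_of_sec[gids],
                          sections_global = gids,
                          u_in = secs$u_rel[secs$parent == 0L][1]),
                     class = if (u$kind == "pipe") "pipe_unit" else "bifurcation_unit")
    obj
  })

  interfaces <- lapply(seq_along(iface_sections), function(i) {
    list(id = i, section = iface_sections[i], units = iface_units[[i]],
         kind = iface_kind[i])
  })
  adjacency <- if (length(interfaces)) {
    data.frame(unit_a = vapply(interfaces, function(x) x$units[1], 0L),
               unit_b = vapply(interfaces, function(x) x$units[2], 0L),
               interface = seq_along(interfaces),
               kind = iface_kind)
  } else {
    data.frame(unit_a = integer(0), unit_b = integer(0),
               interface = integer(0), kind = character(0))
  }

  structure(list(sections = sec_tab, units = units, interfaces = interfaces,
                 adjacency = adjacency, morphology = m,
                 section_spacing = section_spacing),
            class = "structure_graph")
}

#' Build the single stitched template graph of a whole network
#'
#' Instantiates every cross section of the decomposition exactly once,
#' yielding the network-wide graph used by the reference solver for ground
#' truth. The attribute \code{"unit_node_map"} maps each unit-graph node to
#' its network-graph node (interface sections are shared).
#'
#' @param sg a \code{structure_graph}.
#' @return a \code{template_graph} with attribute \code{unit_node_map}.
#' @export
build_network_graph <- function(sg) {
  secs <- sg$sections
  ns <- nrow(secs)
  haschild <- seq_len(ns) %in% secs$parent
  role <- ifelse(secs$parent == 0L, "inlet",
                 ifelse(!haschild, "outlet", "interior"))
  g <- build_graph_from_sections(secs, role, rep(NA_integer_, ns), "network")
  offset <- c(0L, cumsum(secs$nn))
  map <- lapply(sg$units, function(u) {
    unlist(lapply(seq_along(u$sections_global), function(k) {
      offset[u$sections_global[k]] + seq_len(secs$nn[u$sections_global[k]])
    }))
  })
  attr(g, "unit_node_map") <- map
  g
}

#' Unit template graph
#'
#' Dispatches to \code{\link{build_pipe_graph}} or
#' \code{\link{build_bifurcation_graph}} by unit kind.
#'
#' @param u a \code{pipe_unit} or \code{bifurcation_unit}.
#' @param ... passed on.
#' @return a \code{template_graph}.
#' @export
build_unit_graph <- function(u, ...) {
  if (inherits(u, "pipe_unit")) build_pipe_graph(u, ...) else
    build_bifurcation_graph(u, ...)
}

#' @export
print.structure_graph <- function(x, ...) {
  kinds <- vapply(x$units, `[[`, "", "kind")
  cat("Structure graph: ", sum(kinds == "pipe"), " pipe(s), ",
      sum(kinds == "bifurcation"), " bifurcation(s), ",
      length(x$interfaces), " interface(s)\n", sep = "")
  if (nrow(x$adjacency)) {
    cat("  interface kinds:",
        paste(sprintf("%s=%d", names(table(x$adjacency$kind)),
                      table(x$adjacency$kind)), collapse = ", "), "\n")
  }
  invisible(x)
}
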