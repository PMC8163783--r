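test_that("an unbranched chain decomposes to a single pipe", {
  m <- generate_morphology(0, seed = 3)
  sg <- decompose_morphology(m)
  kinds <- vapply(sg$units, `[[`, "", "kind")
  expect_equal(kinds, "pipe")
  expect_length(sg$interfaces, 0L)
})

test_that("a Y-shaped tree gives 1 bifurcation, 3 pipes, 3 interfaces", {
  m <- generate_morphology(1, seed = 11, branch_length_range = c(14, 16))
  sg <- decompose_morphology(m)
  kinds <- vapply(sg$units, `[[`, "", "kind")
  expect_equal(sum(kinds == "bifurcation"), 1L)
  expect_equal(sum(kinds == "pipe"), 3L)
  expect_length(sg$interfaces, 3L)
  expect_true(all(sg$adjacency$kind == "p-b"))
})

test_that("decomposition counts match an independent skeleton traversal", {
  for (s in c(21, 22)) {
    m <- generate_morphology(5, seed = s, branch_length_range = c(14, 20))
    sg <- decompose_morphology(m)
    # oracle: direct traversal of the skeleton tree counting branch points
    # and terminal-to-terminal segments
    idx <- match(m$parent, m$id)
    nkid <- tabulate(idx[!is.na(idx)], nbins = nrow(m))
    n_bp <- sum(nkid >= 2L)
    n_seg <- 0L
    walk_from <- c(which(is.na(idx)), which(nkid >= 2L))
    for (t0 in walk_from) {
      for (c0 in which(idx == t0)) {
        cur <- c0
        while (nkid[cur] == 1L) cur <- which(idx == cur)
        n_seg <- n_seg + 1L
      }
    }
    expect_equal(n_seg, 2L * n_bp + 1L)
    kinds <- vapply(sg$units, `[[`, "", "kind")
    expect_equal(sum(kinds == "bifurcation"), n_bp)
    expect_equal(sum(kinds == "pipe"), 2L * n_bp + 1L)
    expect_length(sg$interfaces, 3L * n_bp)
  }
})

test_that("long pipes split into chunks with pipe-pipe interfaces", {
  m <- generate_morphology(0, seed = 3, branch_length_range = c(30, 30))
  sg <- decompose_morphology(m, max_pipe_sections = 6)
  kinds <- vapply(sg$units, `[[`, "", "kind")
  expect_gt(sum(kinds == "pipe"), 1L)
  expect_true(all(sg$adjacency$kind == "p-p"))
})

test_that("pipe template graphs carry 17 nodes per cross section", {
  p <- pipe_unit(cbind(0, 0, seq(0, 6, by = 0.1)), 1.0)
  g <- build_pipe_graph(p, section_spacing = 2)
  expect_equal(nrow(g$sections), 4L)
  expect_equal(g$n, 68L)  # 4 sections x 17 nodes
  expect_true(all(table(g$sec) == 17L))
  # nodes lie within the local section radius of the section center
  ctr <- as.matrix(g$sections[g$sec, c("cx", "cy", "cz")])
  d <- sqrt(rowSums((g$pos - ctr)^2))
  expect_true(all(d <= g$radius + 1e-9))
})

test_that("pipe graphs are translation-equivariant", {
  v <- c(3, -2, 7)
  p1 <- pipe_unit(cbind(0, 0, seq(0, 6, by = 0.5)), 0.9)
  p2 <- pipe_unit(sweep(cbind(0, 0, seq(0, 6, by = 0.5)), 2, -v), 0.9)
  g1 <- build_pipe_graph(p1, 2)
  g2 <- build_pipe_graph(p2, 2)
  expect_identical(g1$edges, g2$edges)
  expect_equal(sweep(g2$pos, 2, v), g1$pos, tolerance = 1e-12)
})

test_that("bifurcation graphs have 23 branch-point nodes and 176 total", {
  g <- fx_bif_graph()
  expect_equal(g$n, 176L)
  nn <- table(g$sec)
  expect_equal(sum(nn == 23L), 1L)
  expect_equal(sum(nn == 17L), 9L)
  # the branch-point section is the one at the branch point
  bp_sec <- which(g$sections$nn == 23L)
  expect_equal(unlist(g$sections[bp_sec, c("cx", "cy", "cz")]),
               c(cx = 0, cy = 0, cz = 0), tolerance = 1e-9)
  # connectivity: every node reachable from node 1
  adj <- lapply(seq_len(g$n), function(i) integer(0))
  for (r in seq_len(nrow(g$edges))) {
    adj[[g$edges[r, 1]]] <- c(adj[[g$edges[r, 1]]], g$edges[r, 2])
    adj[[g$edges[r, 2]]] <- c(adj[[g$edges[r, 2]]], g$edges[r, 1])
  }
  seen <- logical(g$n); queue <- 1L; seen[1L] <- TRUE
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    new <- adj[[i]][!seen[adj[[i]]]]
    seen[new] <- TRUE; queue <- c(queue, new)
  }
  expect_true(all(seen))
})

test_that("a symmetric bifurcation is invariant under swapping its children", {
  th <- 25 * pi / 180
  stub <- function(dirv, r) list(centers = outer(1:3, dirv), radii = rep(r, 3))
  b1 <- bifurcation_unit(c(0, 0, 0),
                         list(stub(c(0, 0, -1), 1),
                              stub(c(sin(th), 0, cos(th)), 0.7),
                              stub(c(-sin(th), 0, cos(th)), 0.7)))
  b2 <- bifurcation_unit(c(0, 0, 0),
                         list(stub(c(0, 0, -1), 1),
                              stub(c(-sin(th), 0, cos(th)), 0.7),
                              stub(c(sin(th), 0, cos(th)), 0.7)))
  g1 <- build_bifurcation_graph(b1)
  g2 <- build_bifurcation_graph(b2)
  s1 <- g1$pos[order(g1$pos[, 1], g1$pos[, 2], g1$pos[, 3]), ]
  s2 <- g2$pos[order(g2$pos[, 1], g2$pos[, 2], g2$pos[, 3]), ]
  expect_equal(s1, s2, tolerance = 1e-9)
})

test_that("interface node positions coincide between owning units", {
  sg <- fx_sg()
  graphs <- lapply(sg$units, build_unit_graph)
  expect_gt(length(sg$interfaces), 0L)
  for (it in sg$interfaces) {
    ga <- graphs[[it$units[1]]]; gb <- graphs[[it$units[2]]]
    ia <- which(sg$units[[it$units[1]]]$sections_global[ga$sec] == it$section)
    ib <- which(sg$units[[it$units[2]]]$sections_global[gb$sec] == it$section)
    expect_equal(length(ia), 17L)
    expect_lt(max(abs(ga$pos[ia, ] - gb$pos[ib, ])), 1e-9)
  }
})

test_that("counts are invariant under rigid motion of the morphology", {
  m <- fx_morph()
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  m2 <- m
  xyz <- as.matrix(m[, c("x", "y", "z")]) %*% R
  m2$x <- xyz[, 1] + 5; m2$y <- xyz[, 2] - 1; m2$z <- xyz[, 3] + 2
  g1 <- build_network_graph(decompose_morphology(m))
  g2 <- build_network_graph(decompose_morphology(m2))
  expect_equal(g1$n, g2$n)
  expect_equal(nrow(g1$edges), nrow(g2$edges))
  expect_equal(nrow(g1$sections), nrow(g2$sections))
})

test_that("every morphology section belongs to at least one unit", {
  sg <- fx_sg()
  claimed <- sort(unique(unlist(lapply(sg$units, `[[`, "sections_global"))))
  expect_equal(claimed, seq_len(nrow(sg$sections)))
})
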