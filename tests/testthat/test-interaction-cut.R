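test_that("ray-triangle intersection returns parametric hits and misses", {
  tri <- unit_triangle()
  r <- ray(c(0.25, 0.25, 1), c(0, 0, -1))
  hit <- ray_triangle(r, tri$vertices[1L, ], tri$vertices[2L, ], tri$vertices[3L, ])
  expect_equal(hit$t, 1)
  expect_equal(hit$point, c(0.25, 0.25, 0))
  expect_equal(sum(hit$bary), 1)
  expect_true(all(hit$bary >= 0 & hit$bary <= 1))

  # parallel ray and behind-origin hit both miss
  expect_null(ray_triangle(ray(c(0, 0, 1), c(1, 0, 0)),
                           tri$vertices[1L, ], tri$vertices[2L, ],
                           tri$vertices[3L, ]))
  expect_null(ray_triangle(ray(c(0.25, 0.25, -1), c(0, 0, -1)),
                           tri$vertices[1L, ], tri$vertices[2L, ],
                           tri$vertices[3L, ]))
  expect_error(ray(c(0, 0, 0), c(1, 1, 0)), "unit length")
})

test_that("cast_ray picks the nearest face and agrees with brute force", {
  # two stacked sheets: the nearer one wins
  two <- trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                       c(0, 0, 1), c(1, 0, 1), c(0, 1, 1)),
                 rbind(c(1L, 2L, 3L), c(4L, 5L, 6L)))
  hit <- cast_ray(two, ray(c(0.2, 0.2, 5), c(0, 0, -1)))
  expect_equal(hit$face, 2L)
  expect_null(cast_ray(two, ray(c(5, 5, 5), c(0, 0, -1))))

  ico <- make_icosphere(2, 1)
  set.seed(99)
  for (k in 1:100) {
    org <- rnorm(3); org <- 3 * org / sqrt(sum(org^2))
    tgt <- rnorm(3) * 0.3
    r <- ray(org, tgt - org, normalize = TRUE)
    got <- cast_ray(ico, r)
    want <- oracle_cast(ico, r)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$face, want$face)
      expect_equal(got$t, want$t, tolerance = 1e-12)
    }
  }
})

test_that("cut-path marking crosses shared edges and detects closure", {
  q <- flat_quad()
  cen1 <- colMeans(q$vertices[q$faces[1L, ], ])
  cen2 <- colMeans(q$vertices[q$faces[2L, ], ])
  samples <- data.frame(x = c(cen1[1L], cen2[1L]), y = c(cen1[2L], cen2[2L]),
                        z = 0, face = c(1L, 2L))
  cp <- mark_cut_path(q, samples)
  expect_equal(cp$crossed_edges, matrix(c(1L, 2L), 1L), ignore_attr = TRUE)
  expect_false(cp$closed)

  single <- mark_cut_path(q, samples[1L, ])
  expect_equal(nrow(single$crossed_edges), 0L)
  expect_false(single$closed)

  # off-surface sample is rejected with its index
  bad <- samples; bad$z[2L] <- 0.5
  expect_error(mark_cut_path(q, bad), "sample 2")
})

test_that("the scripted boundary loop crosses every label-boundary edge", {
  ph <- make_kidney_phantom()
  topo <- build_edge_topology(ph)
  samples <- plan_boundary_cut(ph, "cancerous", topology = topo)
  cp <- mark_cut_path(ph, samples, topology = topo)
  expect_true(cp$closed)

  lab <- ph$face_labels
  ef <- topo$edge_faces
  interior <- which(!topo$boundary)
  bidx <- interior[lab[ef[interior, 1L]] != lab[ef[interior, 2L]]]
  bkeys <- paste(topo$edges[bidx, 1L], topo$edges[bidx, 2L])
  ckeys <- paste(cp$crossed_edges[, 1L], cp$crossed_edges[, 2L])
  expect_true(all(bkeys %in% ckeys))
  expect_true(all(ckeys %in% paste(topo$edges[, 1L], topo$edges[, 2L])))

  # the boundary edges form a single closed vertex cycle
  be <- topo$edges[bidx, , drop = FALSE]
  g <- igraph::graph_from_edgelist(cbind(match(be[, 1L], unique(c(be))),
                                         match(be[, 2L], unique(c(be)))),
                                   directed = FALSE)
  expect_true(all(igraph::degree(g) == 2L))
  expect_equal(igraph::components(g)$no, 1L)
})

test_that("severing a cut removes its constraints and splits the graph", {
  q <- flat_quad()
  topo <- build_edge_topology(q)
  cfg <- solver_config()
  cons <- make_constraints(topo, cfg)
  cen1 <- colMeans(q$vertices[q$faces[1L, ], ])
  cen2 <- colMeans(q$vertices[q$faces[2L, ], ])
  cp <- mark_cut_path(q, data.frame(x = c(cen1[1L], cen2[1L]),
                                    y = c(cen1[2L], cen2[2L]),
                                    z = 0, face = 1:2))
  out <- apply_cut(cons, cp, mode = "sever")
  expect_equal(nrow(out$stretch), nrow(cons$stretch) - 1L)
  expect_equal(nrow(out$bend), 0L)  # the only dihedral was hinged on the cut

  # weaken mode changes no counts until load is applied
  wk <- apply_cut(cons, cp, mode = "weaken", break_threshold = 0.2)
  expect_equal(nrow(wk$stretch), nrow(cons$stretch))
  expect_true(wk$stretch$breakable[paste(pmin(wk$stretch$i, wk$stretch$j),
                                         pmax(wk$stretch$i, wk$stretch$j)) ==
                                    "1 2"])

  # severing the full tumor loop separates the face-adjacency graph in two
  # (the vertex/constraint graph splits only at resection, when cut-line
  # vertices are duplicated)
  ph <- make_kidney_phantom()
  tph <- build_edge_topology(ph)
  consph <- make_constraints(tph, cfg)
  cpph <- mark_cut_path(ph, plan_boundary_cut(ph, "cancerous", topology = tph),
                        topology = tph)
  cut <- apply_cut(consph, cpph, mode = "sever")
  expect_lte(nrow(cut$stretch), nrow(consph$stretch))
  expect_length(connected_components(ph, drop_edges = cpph$crossed_edges), 2L)
})

test_that("resection separates the quad fixture into its two triangles", {
  q <- flat_quad()
  q$face_labels <- c("cancerous", "healthy")
  cen1 <- colMeans(q$vertices[q$faces[1L, ], ])
  cen2 <- colMeans(q$vertices[q$faces[2L, ], ])
  # closed because first and last samples share face 1
  cp <- mark_cut_path(q, data.frame(x = c(cen1[1L], cen2[1L], cen1[1L]),
                                    y = c(cen1[2L], cen2[2L], cen1[2L]),
                                    z = 0, face = c(1L, 2L, 1L)))
  expect_true(cp$closed)
  out <- resect(q, cp, "cancerous")
  expect_equal(n_faces(out$excised), 1L)
  expect_equal(n_faces(out$remaining), 1L)
  expect_equal(out$report$label_purity, 1)
  # cut-cycle vertices are duplicated into both outputs
  expect_equal(n_vertices(out$excised), 3L)
  expect_equal(n_vertices(out$remaining), 3L)
})

test_that("resection of the phantom excises the labelled region exactly", {
  ph <- make_kidney_phantom()
  topo <- build_edge_topology(ph)
  cp <- mark_cut_path(ph, plan_boundary_cut(ph, "cancerous", topology = topo),
                      topology = topo)
  out <- resect(ph, cp, "cancerous")
  labelled <- which(ph$face_labels == "cancerous")
  expect_setequal(out$excised_faces, labelled)
  expect_equal(out$report$label_purity, 1)
  expect_equal(out$report$label_recall, 1)
  expect_equal(out$report$healthy_damage_count, 0L)
  expect_equal(length(out$excised_faces) + length(out$remaining_faces),
               n_faces(ph))
  expect_equal(out$report$n_components, 2L)

  # an open C-shaped path is rejected
  samples <- plan_boundary_cut(ph, "cancerous", topology = topo)
  open_samples <- samples[seq_len(floor(nrow(samples) / 2)), ]
  cpo <- mark_cut_path(ph, open_samples, topology = topo)
  if (!cpo$closed) expect_error(resect(ph, cpo, "cancerous"), "not closed")

  # a non-separating cut is rejected with a diagnostic
  cp1 <- mark_cut_path(ph, samples[1:2, ], topology = topo)
  cp1$closed <- TRUE  # force past the closure check to probe separation
  expect_error(resect(ph, cp1, "cancerous"), "not separating")
})

test_that("apply_cut never increases the constraint count", {
  ph <- make_kidney_phantom(phantom_spec(subdivision = 2L))
  topo <- build_edge_topology(ph)
  cons <- make_constraints(topo, solver_config())
  cp <- mark_cut_path(ph, plan_boundary_cut(ph, "cancerous", topology = topo),
                      topology = topo)
  for (mode in c("sever", "weaken")) {
    out <- apply_cut(cons, cp, mode = mode)
    expect_lte(nrow(out$stretch), nrow(cons$stretch))
    expect_lte(nrow(out$bend), nrow(cons$bend))
  }
})
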