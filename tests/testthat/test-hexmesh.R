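test_that("voxel connectivity: node counts, sharing and watertightness", {
  # single foreground voxel
  v1 <- labeled_volume(array(1L, c(1, 1, 1)), spacing = rep(2e-3, 3))
  m1 <- build_hex_mesh(v1)
  expect_equal(nrow(m1$elements), 1L)
  expect_equal(nrow(m1$nodes), 8L)
  # two face-adjacent voxels share exactly 4 nodes
  arr <- array(0L, c(2, 1, 1)); arr[] <- 1L
  m2 <- build_hex_mesh(labeled_volume(arr, spacing = rep(2e-3, 3)))
  expect_equal(nrow(m2$elements), 2L)
  expect_equal(nrow(m2$nodes), 12L)
  expect_equal(length(intersect(m2$elements[1, ], m2$elements[2, ])), 4L)
  # phantom mesh: one element per foreground voxel, all unit cells
  ph <- phantom_fixture()
  mesh <- ph$mesh
  expect_equal(nrow(mesh$elements), sum(ph$phantom$volume$labels > 0))
  # watertight: every pair of face-adjacent elements shares exactly 4 nodes
  key <- mesh$element_cell
  idx <- key[, 1] + mesh$resolution[1] * (key[, 2] + mesh$resolution[2] * key[, 3])
  lookup <- integer(prod(mesh$resolution)); lookup[idx + 1] <- seq_len(nrow(key))
  shifts <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  for (s in 1:3) {
    nb <- sweep(key, 2, shifts[s, ], "+")
    inside <- nb[, 1] < mesh$resolution[1] & nb[, 2] < mesh$resolution[2] &
      nb[, 3] < mesh$resolution[3]
    nbid <- lookup[nb[inside, 1] + mesh$resolution[1] *
                   (nb[inside, 2] + mesh$resolution[2] * nb[inside, 3]) + 1]
    here <- which(inside)[nbid > 0]
    nbid <- nbid[nbid > 0]
    shared <- vapply(seq_along(here), function(i)
      length(intersect(mesh$elements[here[i], ], mesh$elements[nbid[i], ])),
      integer(1))
    expect_true(all(shared == 4L))
  }
})

test_that("element volumes tile the foreground exactly", {
  ph <- phantom_fixture()
  mesh <- ph$mesh
  cellv <- prod(mesh$spacing)
  # every element is an axis-aligned cube of identical edges
  e1 <- mesh$elements[7, ]
  edges <- mesh$nodes[e1[c(2, 4, 5)], ] - mesh$nodes[rep(e1[1], 3), ]
  expect_equal(abs(edges), diag(mesh$spacing), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(nrow(mesh$elements) * cellv,
               sum(ph$phantom$volume$labels > 0) * cellv)
})

test_that("build_hex_mesh validates foreground and resolution", {
  empty <- labeled_volume(array(0L, c(3, 3, 3)), spacing = rep(1e-3, 3))
  expect_error(build_hex_mesh(empty), "no foreground")
  vol <- block_volume(c(4, 4, 4))
  expect_error(build_hex_mesh(vol, c(8, 4, 4)), "exceeds")
  expect_error(build_hex_mesh(vol, c(3, 4, 4)), "not divisible")
})

test_that("majority-label coarsening follows the lesion-priority tie-break", {
  # 14 parenchyma / 13 tumor -> strict majority parenchyma
  arr <- array(1L, c(3, 3, 3))
  arr[seq_len(27) <= 13] <- 3L
  vol <- labeled_volume(arr, spacing = rep(1e-3, 3))
  down <- downsample_volume(vol, c(1, 1, 1))
  expect_equal(as.integer(down$labels), 1L)
  # 4/4 parenchyma-tumor tie in a 2x2x2 block -> tumor wins
  arr2 <- array(1L, c(2, 2, 2)); arr2[1:4] <- 3L
  down2 <- downsample_volume(labeled_volume(arr2, rep(1e-3, 3)), c(1, 1, 1))
  expect_equal(as.integer(down2$labels), 3L)
  # vessel beats parenchyma on a tie but loses to tumor
  arr3 <- array(1L, c(2, 2, 2)); arr3[1:4] <- 2L
  expect_equal(as.integer(downsample_volume(
    labeled_volume(arr3, rep(1e-3, 3)), c(1, 1, 1))$labels), 2L)
})

test_that("coarsening agrees with a brute-force per-block histogram", {
  set.seed(42)
  for (rep in 1:5) {
    arr <- array(sample(0:3, 6 * 4 * 4, replace = TRUE, prob = c(.3, .4, .15, .15)),
                 c(6, 4, 4))
    if (!any(arr > 0)) next
    vol <- labeled_volume(arr, spacing = rep(1e-3, 3))
    fine <- build_hex_mesh(vol)
    res <- coarsen_mesh(fine, c(3, 2, 2))
    for (e in seq_len(nrow(res$mesh$elements))) {
      cell <- res$mesh$element_cell[e, ]
      block <- arr[cell[1] * 2 + 1:2, cell[2] * 2 + 1:2, cell[3] * 2 + 1:2]
      counts <- tabulate(block[block > 0], nbins = 3)
      best <- max(counts)
      expected <- c(3L, 2L, 1L)[which(counts[c(3, 2, 1)] == best)[1]]
      expect_equal(res$mesh$element_label[e], expected)
    }
    # a coarse element exists iff its block has >= 1 foreground fine cell
    nblocks_fg <- sum(apply(expand.grid(0:2, 0:1, 0:1), 1, function(b)
      any(arr[b[1] * 2 + 1:2, b[2] * 2 + 1:2, b[3] * 2 + 1:2] > 0)))
    expect_equal(nrow(res$mesh$elements), nblocks_fg)
  }
})

test_that("coarse nodes coincide with their corresponding fine nodes", {
  ph <- phantom_fixture()
  res <- coarsen_mesh(ph$mesh, c(8, 4, 6))
  ok <- !is.na(res$correspondence)
  expect_gt(sum(ok), 0)
  d <- sqrt(rowSums((res$mesh$nodes[ok, , drop = FALSE] -
                     ph$mesh$nodes[res$correspondence[ok], , drop = FALSE])^2))
  expect_lt(max(d), 1e-12)
  expect_error(coarsen_mesh(ph$mesh, c(7, 4, 6)), "divisible")
})

test_that("landmark embedding inverts the trilinear map", {
  mesh <- build_hex_mesh(block_volume(c(3, 3, 3)))
  sp <- mesh$spacing[1]
  # element center: all 8 weights equal 1/8
  center <- landmark_set("c", 1.5 * sp, 1.5 * sp, 1.5 * sp, "surface")
  emb <- embed_landmarks(mesh, center)
  expect_equal(c(emb$xi, emb$eta, emb$zeta), c(0, 0, 0), tolerance = 1e-12)
  # a landmark at a node gets weight 1 there
  nodelm <- landmark_set("n", sp, sp, sp, "surface")
  embn <- embed_landmarks(mesh, nodelm)
  w <- tledreg:::trilinear_weights(embn$xi, embn$eta, embn$zeta)
  expect_equal(sort(w, decreasing = TRUE)[1], 1, tolerance = 1e-12)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  # 100 random interior points reconstruct to < 1e-10 m
  set.seed(7)
  pts <- matrix(runif(300, 0.01, 0.99), 100, 3) * 3 * sp
  lms <- landmark_set(sprintf("r%03d", 1:100), pts[, 1], pts[, 2], pts[, 3],
                      "surface")
  embr <- embed_landmarks(mesh, lms)
  rec <- interpolate_landmarks(mesh, embr)
  expect_lt(max(abs(rec - pts)), 1e-10)
  # a landmark outside every element errors with its id
  expect_error(embed_landmarks(mesh, landmark_set("far", 1, 1, 1, "surface")),
               "far")
})

test_that("phantom landmarks embed in the phantom mesh", {
  ph <- phantom_fixture()
  emb <- embed_landmarks(ph$mesh, ph$phantom$landmarks)
  rec <- interpolate_landmarks(ph$mesh, emb)
  expect_lt(max(abs(rec - lmm(ph$phantom$landmarks))), 1e-10)
})
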