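# small but complete coarse-to-fine setup on the embedded-tumor block
c2f_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      vol <- embedded_tumor_volume(6, 3)   # 6^3 cells, centered 3^3 tumor
      mesh <- build_hex_mesh(vol)
      cfg <- test_config()
      fine <- deformable_model(mesh, cfg)
      cres <- coarsen_mesh(mesh, c(3, 3, 3))
      coarse <- deformable_model(cres$mesh, cfg, coupling = "direct")
      cache <<- list(vol = vol, mesh = mesh, cfg = cfg, fine = fine,
                     coarse = coarse)
    }
    cache
  }
})

test_that("8-vertex shape fits honor node, centroid and reconstruction cases", {
  cube <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))[, c(1, 2, 3)] * 1e-2
  # vertex coincidence: weight 1 there
  w <- fit_element_shapefuns(cube[3, ], cube)
  expect_equal(w[3], 1, tolerance = 1e-10)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  # centroid of the undeformed cube: all weights 1/8
  wc <- fit_element_shapefuns(colMeans(cube), cube)
  expect_equal(wc, rep(1 / 8, 8), tolerance = 1e-10)
  # random interior points reconstruct through Phi' P
  set.seed(11)
  for (i in 1:20) {
    p <- runif(3, 0.1, 0.9) * 1e-2
    wi <- fit_element_shapefuns(p, cube)
    expect_lt(max(abs(as.numeric(wi %*% cube) - p)), 1e-8)
  }
  # deformed element vertices still reconstruct the query exactly
  def <- cube + matrix(rnorm(24, sd = 1e-3), 8, 3)
  p2 <- colMeans(def) + c(1e-3, -5e-4, 2e-4)
  w2 <- fit_element_shapefuns(p2, def)
  expect_lt(max(abs(as.numeric(w2 %*% def) - p2)), 1e-8)
  expect_error(fit_element_shapefuns(rep(5e-3, 3), cube[c(1, 1, 1, 1, 2, 2, 3, 3), ]),
               "collapsed")
})

test_that("the database stores one self-consistent record per condition", {
  fx <- c2f_fixture()
  conds <- list()
  for (m in c(0, 1e-3, 2e-3)) for (dir in list(c(0, 0, -1), c(0.15, 0, -1)))
    conds[[length(conds) + 1]] <- compression_condition(
      1L, c(15e-3, 15e-3, 30e-3), 8e-3, dir, m)
  db <- build_enrichment_database(fx$fine, fx$coarse, conds, coupling_params())
  expect_equal(length(db$records), 6L)  # product of the condition grid
  for (rec in db$records) {
    # partition of unity of every stored shape set
    expect_lt(max(abs(rowSums(rec$weights) - 1)), 1e-10)
    # Eq.-10 self-reconstruction at the fit-time coarse state
    synth <- synthesize_fine(db, rec, rec$coarse_u, fx$coarse$mesh)
    expect_lt(max(abs(synth - rec$fine_positions)), 1e-8)
  }
  # the zero-magnitude record reproduces the rest fine positions
  rec0 <- db$records[[which(vapply(db$records, function(r)
    r$condition$magnitude, numeric(1)) == 0)[1]]]
  # both sides of a split vertex share the rest position, so the rest
  # positions of all entries are just their node coordinates
  rest <- fx$mesh$nodes[db$entries$node, , drop = FALSE]
  expect_lt(max(abs(rec0$fine_positions - rest)), 1e-10)
})

test_that("condition lookup picks the nearest record with deterministic ties", {
  fx <- c2f_fixture()
  mk <- function(mag, dir = c(0, 0, -1)) compression_condition(
    1L, c(15e-3, 15e-3, 30e-3), 8e-3, dir, mag)
  conds <- list(mk(1e-3), mk(3e-3), mk(2e-3, c(0.2, 0, -1)))
  db <- build_enrichment_database(fx$fine, fx$coarse, conds, coupling_params())
  # exact hit
  hit <- lookup_condition(db, mk(3e-3))
  expect_equal(hit$condition$magnitude, 3e-3)
  expect_equal(attr(hit, "distance"), 0)
  # nearer magnitude wins
  near <- lookup_condition(db, mk(1.4e-3))
  expect_equal(near$condition$magnitude, 1e-3)
  # equidistant in the metric: lowest record id wins
  tie <- lookup_condition(db, mk(2e-3))
  expect_equal(tie$id, 1L)
  expect_error(lookup_condition(list(records = list()), mk(1e-3)), "empty")
})

test_that("synthesis is exactly equivariant under rigid coarse translation", {
  fx <- c2f_fixture()
  conds <- list(compression_condition(1L, c(15e-3, 15e-3, 30e-3), 8e-3,
                                      c(0, 0, -1), 1.5e-3))
  db <- build_enrichment_database(fx$fine, fx$coarse, conds, coupling_params())
  rec <- db$records[[1]]
  d <- c(2e-3, -1e-3, 4e-3)
  base <- synthesize_fine(db, rec, rec$coarse_u, fx$coarse$mesh)
  shifted <- synthesize_fine(db, rec,
                             rec$coarse_u + matrix(rep(d, each = nrow(rec$coarse_u)),
                                                   ncol = 3),
                             fx$coarse$mesh)
  expect_equal(shifted, base + matrix(rep(d, each = nrow(base)), ncol = 3),
               tolerance = 1e-10)
})

test_that("coarse-to-fine registration round-trips landmarks and the database survives JSON", {
  fx <- c2f_fixture()
  lms <- landmark_set(c("s1", "t1", "t2"),
                      c(7.5e-3, 12.5e-3, 17.5e-3),
                      c(7.5e-3, 12.5e-3, 12.5e-3),
                      c(7.5e-3, 12.5e-3, 17.5e-3),
                      c("surface", "internal-tumor", "internal-tumor"))
  mk <- function(mag) compression_condition(1L, c(15e-3, 15e-3, 30e-3), 8e-3,
                                            c(0, 0, -1), mag)
  db <- build_enrichment_database(fx$fine, fx$coarse, list(mk(0), mk(1.5e-3)),
                                  coupling_params())
  # zero scenario: identity field, landmarks unmoved
  res0 <- register_coarse_to_fine(fx$coarse, fx$fine, db, mk(0), lms)
  expect_equal(lmm(res0$predicted), lmm(lms), tolerance = 1e-7)
  expect_equal(nrow(res0$predicted), nrow(lms))
  # JSON round trip preserves records to the stored precision
  path <- file.path(withr::local_tempdir(), "db.json")
  write_enrichment_db(db, path)
  back <- read_enrichment_db(path)
  expect_equal(length(back$records), length(db$records))
  expect_equal(back$records[[2]]$condition$magnitude, 1.5e-3)
  expect_equal(back$records[[2]]$weights, db$records[[2]]$weights,
               tolerance = 1e-6)
  expect_equal(back$records[[2]]$fine_positions, db$records[[2]]$fine_positions,
               tolerance = 1e-12)
  expect_identical(back$meta$fine_hash, db$meta$fine_hash)
  # a database built against a different mesh is rejected
  other <- deformable_model(build_hex_mesh(embedded_tumor_volume(4, 2)),
                            test_config(), coupling = "direct")
  expect_error(register_coarse_to_fine(other, fx$fine, db, mk(0), lms),
               "different coarse mesh")
})
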