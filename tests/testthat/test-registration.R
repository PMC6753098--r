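# Registration tests run on a reduced grid so the multi-seed properties stay
# fast; the full-size behaviour is exercised by the pipeline tests.

reg_phantom <- function(seed = 1, dim = c(48, 48, 7)) {
  ph <- make_phantom(phantom_config(grid_dim = dim), seed = seed)
  tr <- ph$truth
  W <- tr$m0 * (1 - ifelse(is.na(tr$baseline_fsf), 0, tr$baseline_fsf) / 100)
  list(W = W, body = tr$masks$body, truth = tr)
}

test_that("registering a volume to itself yields a null field", {
  p <- reg_phantom(1)
  u <- register_nonrigid(p$W, p$W)
  expect_lt(max(abs(u)), 0.01)
})

test_that("pure in-plane translations are recovered at the 3-4-5 scale", {
  p <- reg_phantom(2)
  u <- array(0, c(dim(p$W), 3)); u[, , , 1] <- 3; u[, , , 2] <- 4
  moving <- batlipid:::warp_array(p$W, u, clamp = FALSE)
  moving[is.na(moving)] <- 0
  rec <- register_nonrigid(p$W, moving)
  mag <- sqrt(rec[, , , 1]^2 + rec[, , , 2]^2)
  expect_equal(mean(mag[p$body]), 5, tolerance = 0.5)
})

test_that("smooth synthetic fields are recovered to sub-voxel accuracy", {
  p <- reg_phantom(3)
  d <- dim(p$W)
  set.seed(30)
  u <- array(0, c(d, 3))
  for (c3 in 1:2) {
    raw <- batlipid:::gauss_smooth3(array(rnorm(prod(d)), d), c(6, 6, 1.5))
    u[, , , c3] <- raw / max(abs(raw)) * 2
  }
  moving <- batlipid:::warp_array(p$W, u)
  rec <- register_nonrigid(p$W, moving)
  err2 <- (rec[, , , 1] - u[, , , 1])^2 + (rec[, , , 2] - u[, , , 2])^2 +
    (rec[, , , 3] - u[, , , 3])^2
  expect_lt(sqrt(mean(err2[p$body])), 0.5)
  expect_error(register_nonrigid(p$W, p$W[, , 1:3]), "shape")
})

test_that("registration reduces median fiducial error across seeds", {
  for (seed in 1:5) {
    p <- reg_phantom(seed)
    d <- dim(p$W)
    ser <- echo_series(array(complex(real = p$W), c(d, 1)),
                       build_echo_schedule(1, 1, 1, 1))
    mv <- apply_motion(ser, list(type = "smooth", amplitude = 2), seed = seed + 50)
    moving <- Re(mv$series$data[, , , 1])
    rec <- register_nonrigid(p$W, moving)
    g <- batlipid:::gradient3(p$W)
    gm <- sqrt(g[[1]]^2 + g[[2]]^2); gm[!p$body] <- 0
    ord <- order(gm, decreasing = TRUE)[seq(1, 200, by = 22)][1:9]
    pts <- cbind((ord - 1) %% d[1] + 1,
                 ((ord - 1) %/% d[1]) %% d[2] + 1,
                 (ord - 1) %/% (d[1] * d[2]) + 1)
    before <- transform_points(mv$field, pts)
    after <- transform_points(rec, before)
    fid <- function(m) fiducial_set(cbind(m[, 3], m[, 1], m[, 2]))
    rep_ <- validate_fiducials(fid(pts), fid(before), fid(after))
    expect_lt(attr(rep_, "median_after"), attr(rep_, "median_before"))
  }
})

test_that("fiducial reports compute in-plane distances and catch label mismatch", {
  fixed <- fiducial_set(cbind(c(3, 5), c(10, 12), c(10, 12)))
  same <- validate_fiducials(fixed, fixed, fixed)
  expect_equal(attr(same, "median_before"), 0)
  expect_equal(attr(same, "median_after"), 0)

  moved <- fiducial_set(cbind(c(3, 5), c(13, 15), c(14, 16)))  # (3,4) shift
  rep_ <- validate_fiducials(fixed, moved, fixed)
  expect_equal(attr(rep_, "median_before"), 5)
  expect_equal(rep_$dist_before, c(5, 5))

  bad <- fiducial_set(cbind(c(3, 5), c(10, 12), c(10, 12)), labels = c("a", "b"))
  expect_error(validate_fiducials(fixed, bad, fixed), "labels")
})

test_that("FSF warping respects validity, identity and integer shifts", {
  set.seed(9)
  d <- c(12, 12, 3)
  vals <- array(runif(prod(d), 0, 100), d)
  valid <- array(TRUE, d); valid[1, 1, 1] <- FALSE
  fv <- fsf_volume(ifelse(valid, vals, NA), valid)

  ident <- structure(array(0, c(d, 3)), class = "deformation_field")
  w0 <- warp_fsf(fv, ident)
  expect_identical(w0$fsf, fv$fsf)

  u <- array(0, c(d, 3)); u[, , , 1] <- 2
  w2 <- warp_fsf(fv, structure(u, class = "deformation_field"))
  expect_equal(w2$fsf[1:10, , ], fv$fsf[3:12, , ])
  expect_false(any(w2$valid[11:12, , ]))  # shifted outside the grid

  # warp / inverse-warp self-consistency on a smooth map
  sm <- batlipid:::gauss_smooth3(array(runif(prod(d), 30, 70), d), c(2, 2, 1))
  fs <- fsf_volume(sm, array(TRUE, d))
  us <- array(0, c(d, 3))
  us[, , , 1] <- 0.8; us[, , , 2] <- -0.6
  back <- -us
  w <- warp_fsf(fs, structure(us, class = "deformation_field"))
  wb <- warp_fsf(w, structure(back, class = "deformation_field"))
  core <- wb$valid & !is.na(wb$fsf)
  core[c(1, 2, 11, 12), , ] <- FALSE; core[, c(1, 2, 11, 12), ] <- FALSE
  expect_lt(sqrt(mean((wb$fsf[core] - fs$fsf[core])^2)), 0.5)
  expect_true(all(w$fsf[w$valid] >= 0 & w$fsf[w$valid] <= 100))
})

test_that("slice constraint retains the inclusive 1-based range", {
  vol <- array(seq_len(16 * 16 * 15), c(16, 16, 15))
  v <- constrain_slices(vol, 6, 13)
  expect_equal(dim(v)[3], 8)
  expect_equal(v[, , 1], vol[, , 6])
  expect_equal(dim(constrain_slices(vol, 1, 15))[3], 15)
  expect_error(constrain_slices(vol, 6, 5), "invalid")
  expect_error(constrain_slices(vol, 0, 13), "invalid")
  expect_error(constrain_slices(vol, 6, 16), "invalid")

  fv <- fsf_volume(array(50, c(4, 4, 15)), array(TRUE, c(4, 4, 15)))
  expect_equal(dim(constrain_slices(fv, 6, 13)$fsf)[3], 8)
})
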