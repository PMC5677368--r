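square <- cbind(x = c(10, 110, 110, 10), y = c(10, 10, 110, 110))

test_that("shoelace areas and atlas validation behave", {
  expect_equal(polygon_area_px2(square), 100 * 100)
  # 100-px square at 1 um/px is 0.01 mm^2
  atlas1 <- region_atlas("ROSTRAL", 1, list(sq = square))
  expect_equal(region_counts(data.frame(centroid_x = numeric(0),
                                        centroid_y = numeric(0),
                                        region = character(0)),
                             atlas1)$area_mm2[1], 0.01)
  expect_error(region_atlas("MEDIAL", 0, list(sq = square)), "> 0")
  expect_error(region_atlas("MEDIAL", 1, list(cbind(1:3, 1:3))), "named")
})

test_that("point-in-polygon matches an independent implementation", {
  skip_if_not_installed("pracma")
  atlas <- synthetic_atlas()
  set.seed(17)
  px <- runif(10000, 0, 600); py <- runif(10000, 0, 400)
  for (v in atlas$regions) {
    mine <- point_in_polygon(px, py, v)
    ref <- pracma::inpolygon(px, py, v[, 1], v[, 2], boundary = TRUE)
    expect_identical(mine, ref)
  }
})

test_that("containment is boundary inclusive at vertices and edges", {
  expect_true(point_in_polygon(10, 10, square))    # vertex
  expect_true(point_in_polygon(60, 10, square))    # edge midpoint
  expect_true(point_in_polygon(110, 60, square))   # right edge
  expect_true(point_in_polygon(60, 60, square))    # interior
  expect_false(point_in_polygon(9.999, 60, square))
  expect_false(point_in_polygon(111, 60, square))
  # concave polygon: notch excluded
  notch <- cbind(x = c(0, 10, 10, 5, 5, 0), y = c(0, 0, 10, 10, 5, 5))
  expect_true(point_in_polygon(2, 2, notch))
  expect_true(point_in_polygon(7, 7, notch))   # inside the tall arm
  expect_false(point_in_polygon(2, 7, notch))  # inside the notch cut-out
})

test_that("section-image generator plants Poisson counts with ground truth", {
  atlas <- synthetic_atlas()
  blank <- generate_section_image(atlas, per_region_density = 0,
                                  noise_sd = 0, seed = 1)
  expect_identical(nrow(blank$truth), 0L)
  expect_identical(max(blank$image), 0)
  # expected count = density x area within Poisson error
  dens <- 1500
  total_area <- sum(vapply(atlas$regions, polygon_area_px2, 0)) *
    (atlas$pixel_size_um / 1000)^2
  sec <- generate_section_image(atlas, per_region_density = dens, seed = 2)
  lambda <- dens * total_area
  expect_lt(abs(nrow(sec$truth) - lambda), 4 * sqrt(lambda))
  # every planted soma lies inside its named region
  for (nm in unique(sec$truth$region)) {
    pts <- sec$truth[sec$truth$region == nm, ]
    expect_true(all(point_in_polygon(pts$x, pts$y, atlas$regions[[nm]])))
  }
  # determinism
  sec2 <- generate_section_image(atlas, per_region_density = dens, seed = 2)
  expect_identical(sec$image, sec2$image)
})

test_that("soma detection finds well-separated blobs with sub-pixel centroids", {
  set.seed(33)
  gx <- rep(seq(20, 380, by = 40), each = 10)
  gy <- rep(seq(20, 380, by = 40), times = 10)
  xs <- gx + runif(100, -3, 3)
  ys <- gy + runif(100, -3, 3)
  img <- render_blobs(xs, ys, 400, 400, sigma = 2, peak = 0.8,
                      noise_sd = 0.02)
  det <- detect_somata(img, min_area_px2 = 4)
  expect_identical(nrow(det), 100L)
  err <- vapply(seq_len(nrow(det)), function(i)
    min(sqrt((xs - det$centroid_x[i])^2 + (ys - det$centroid_y[i])^2)), 0)
  expect_lt(max(err), 1)
  # blank image: zero detections
  expect_identical(nrow(detect_somata(matrix(0, 50, 50),
                                      threshold_mode = 0)), 0L)
  # area filter rejects small components
  one <- matrix(0, 40, 40); one[20, 20] <- 1; one[30, 29:31] <- 1
  d <- detect_somata(one, threshold_mode = 0.5, min_area_px2 = 2)
  expect_identical(nrow(d), 1L)
  expect_equal(d$area_px2, 3)
  expect_error(detect_somata(one, threshold_mode = 5), "range")
})

test_that("labelling is 8-connected", {
  img <- matrix(0, 20, 20)
  img[5, 5] <- 1; img[6, 6] <- 1; img[7, 5] <- 1  # diagonal chain
  det <- detect_somata(img, threshold_mode = 0.5, min_area_px2 = 1)
  expect_identical(nrow(det), 1L)
  expect_equal(det$area_px2, 3)
})

test_that("region assignment is first-wins with unassigned fallback", {
  atlas <- synthetic_atlas()
  inside_dls <- data.frame(centroid_x = 0.8 * 600, centroid_y = 0.45 * 400)
  expect_identical(assign_regions(inside_dls, atlas)$region, "DLS")
  outside <- data.frame(centroid_x = 599, centroid_y = 399)
  expect_identical(assign_regions(outside, atlas)$region, "UNASSIGNED")
  # overlapping polygons: first in atlas order wins, with a warning
  ov <- region_atlas("MEDIAL", 1, list(a = square, b = square + 50))
  pt <- data.frame(centroid_x = 80, centroid_y = 80)  # inside both
  expect_warning(lab <- assign_regions(pt, ov), "overlap")
  expect_identical(lab$region, "a")
})

test_that("region counts conserve totals and recover planted densities", {
  atlas <- synthetic_atlas(width = 1200, height = 800)
  sec <- generate_section_image(atlas, per_region_density = 120,
                                soma_radius_px = 2, seed = 4,
                                width = 1200, height = 800)
  det <- assign_regions(detect_somata(sec$image, min_area_px2 = 4), atlas)
  rc <- region_counts(det, atlas)
  expect_identical(sum(rc$count), nrow(det))
  # planted count recovered within 5 percent overall
  expect_lt(abs(sum(rc$count[rc$region != "UNASSIGNED"]) - nrow(sec$truth)) /
              nrow(sec$truth), 0.05)
  # per-region densities within Poisson confidence of the planted density
  for (i in which(rc$region != "UNASSIGNED")) {
    lam <- 120 * rc$area_mm2[i]
    expect_lt(abs(rc$count[i] - lam), 4 * sqrt(lam) + 3)
  }
})

test_that("cross-correlation matrices have Pearson structure", {
  set.seed(12)
  m <- matrix(rpois(6 * 40, 30), 40, 6,
              dimnames = list(NULL, paste0("r", 1:6)))
  m <- cbind(m, dup = m[, 1])  # duplicated column correlates exactly
  cc <- cross_correlation_matrix(m)
  expect_equal(cc$r["r1", "dup"], 1)
  expect_equal(cc$r, t(cc$r))
  expect_true(all(diag(cc$r) == 1))
  expect_true(all(is.na(diag(cc$p))))
  # r and p agree with cor.test on a sampled pair
  ct <- cor.test(m[, 2], m[, 3])
  expect_equal(cc$r["r2", "r3"], unname(ct$estimate))
  expect_equal(cc$p["r2", "r3"], ct$p.value)
  # planted correlation recovered within its Fisher-z interval
  set.seed(13)
  n <- 50; rho <- 0.9
  x <- rnorm(n); y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  cc2 <- cross_correlation_matrix(cbind(a = x, b = y))
  z <- atanh(cc2$r["a", "b"])
  ci <- tanh(z + c(-1, 1) * 1.96 / sqrt(n - 3))
  expect_true(rho >= ci[1] && rho <= ci[2])
  expect_error(cross_correlation_matrix(m[1:2, ]), "at least 3")
})

test_that("activity-performance correlations handle degenerate features", {
  set.seed(14)
  counts <- matrix(rpois(4 * 20, 50), 20, 4,
                   dimnames = list(NULL, c("DLS", "DMS", "PrL", "FPx")))
  feats <- cbind(speed = counts[, "DLS"],       # exact copy: r = 1
                 const = rep(3, 20),            # undefined: NA
                 noise = rnorm(20))
  ap <- activity_performance_correlation(counts, feats)
  expect_equal(ap$r["DLS", "speed"], 1)
  expect_true(is.na(ap$r["DLS", "const"]))
  # planted linear relation: sign-consistent and inside the Fisher interval
  slope_feat <- 2 * counts[, "DMS"] + rnorm(20, sd = 4)
  ap2 <- activity_performance_correlation(counts, cbind(f = slope_feat))
  r <- ap2$r["DMS", "f"]
  expect_gt(r, 0)
  truth_r <- cor(counts[, "DMS"], slope_feat)
  expect_equal(r, truth_r)
})

test_that("reconstruction exports round-trip with consistent geometry", {
  atlas <- synthetic_atlas()
  sec <- generate_section_image(atlas, per_region_density = 600, seed = 6)
  det <- assign_regions(detect_somata(sec$image, min_area_px2 = 4), atlas)
  map <- reconstruct_map(det, atlas)
  expect_identical(nrow(map$points), nrow(det))
  f <- tempfile(fileext = ".geojson")
  write_map_geojson(map, f)
  back <- read_map_geojson(f)
  expect_identical(names(back$outlines), names(map$outlines))
  expect_equal(back$points$x, map$points$x)
  expect_identical(back$points$region, map$points$region)
  # every assigned exported point lies inside its tagged polygon
  for (nm in setdiff(unique(back$points$region), "UNASSIGNED")) {
    pts <- back$points[back$points$region == nm, ]
    expect_true(all(point_in_polygon(pts$x, pts$y, atlas$regions[[nm]])))
  }
})

test_that("atlas JSON and section TIFF round-trip", {
  atlas <- synthetic_atlas()
  fa <- tempfile(fileext = ".json")
  write_atlas_json(atlas, fa)
  back <- read_atlas_json(fa)
  expect_identical(back$level, atlas$level)
  expect_equal(back$pixel_size_um, atlas$pixel_size_um)
  expect_equal(back$regions, atlas$regions)
  img <- render_blobs(c(20, 40), c(25, 10), 64, 48, sigma = 2)
  ft <- tempfile(fileext = ".tif")
  write_section_tiff(img, ft)
  expect_lt(max(abs(read_section_tiff(ft) - img)), 1 / 65535)
})
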