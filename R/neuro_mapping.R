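#' Construct a polygonal region atlas
#'
#' An atlas names the closed polygonal outlines of the cortical and
#' striatal regions analysed on one section level (rostral, medial or
#' caudal). Vertices are pixel coordinates under the image convention:
#' origin at the top-left pixel centre, x rightward, y downward, 0-based.
#'
#' @param level `"ROSTRAL"`, `"MEDIAL"` or `"CAUDAL"`.
#' @param pixel_size_um Pixel size in micrometres per pixel.
#' @param regions Named list of vertex matrices (n x 2, columns x, y);
#'   polygons are closed implicitly (last vertex joins the first).
#' @return A `region_atlas` object.
#' @export
region_atlas <- function(level, pixel_size_um, regions) {
  level <- match.arg(level, c("ROSTRAL", "MEDIAL", "CAUDAL"))
  if (pixel_size_um <= 0) stop("pixel_size_um must be > 0")
  if (is.null(names(regions)) || any(!nzchar(names(regions))))
    stop("regions must be a named list")
  regions <- lapply(regions, function(v) {
    v <- as.matrix(v)
    if (ncol(v) != 2 || nrow(v) < 3) stop("each region needs >= 3 (x, y) vertices")
    colnames(v) <- c("x", "y")
    if (polygon_area_px2(v) <= 0) stop("region area must be > 0")
    v
  })
  structure(list(level = level, pixel_size_um = pixel_size_um,
                 regions = regions), class = "region_atlas")
}

#' Polygon area by the shoelace formula
#'
#' @param vertices n x 2 matrix of (x, y) vertices of a simple closed
#'   polygon (closure implicit).
#' @return Area in squared pixels (always positive).
#' @export
polygon_area_px2 <- function(vertices) {
  x <- vertices[, 1]; y <- vertices[, 2]
  j <- c(seq_len(nrow(vertices))[-1], 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Point-in-polygon test (ray casting, boundary inclusive)
#'
#' Vectorised crossing-number test with an explicit boundary convention:
#' points lying on a polygon edge or vertex count as inside. This is the
#' containment rule used for atlas region assignment.
#'
#' @param px,py Point coordinates (equal-length vectors).
#' @param vertices n x 2 polygon vertex matrix (closure implicit).
#' @param eps Distance tolerance for the on-boundary test.
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, vertices, eps = 1e-9) {
  x <- vertices[, 1]; y <- vertices[, 2]
  nv <- length(x)
  jj <- c(nv, seq_len(nv - 1))
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  for (k in seq_len(nv)) {
    x1 <- x[jj[k]]; y1 <- y[jj[k]]; x2 <- x[k]; y2 <- y[k]
    # on-segment test: collinear and within the bounding box
    cross <- (px - x1) * (y2 - y1) - (py - y1) * (x2 - x1)
    seg_len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
    dist <- abs(cross) / max(seg_len, eps)
    within <- px >= pmin(x1, x2) - eps & px <= pmax(x1, x2) + eps &
      py >= pmin(y1, y2) - eps & py <= pmax(y1, y2) + eps
    on_edge <- on_edge | (dist <= eps & within)
    # crossing-number update (half-open rule avoids double-counting vertices)
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
  }
  inside | on_edge
}

#' Synthetic demonstration atlas
#'
#' A synthetic stand-in for a manually drawn section atlas: eight
#' non-overlapping convex polygons named after the regions quantified in
#' activation mapping (PrL, aCg/M2, aDS, Core, Shell, DMS, DLS, FPx),
#' laid out on a `width` x `height` pixel canvas. Geometry is invented for
#' testing and demonstration; it is not anatomical.
#'
#' @param level Atlas level tag.
#' @param pixel_size_um Pixel size (µm/px).
#' @param width,height Canvas size in pixels.
#' @return A [region_atlas()].
#' @export
synthetic_atlas <- function(level = "MEDIAL", pixel_size_um = 1.6,
                            width = 600, height = 400) {
  w <- width; h <- height
  box <- function(x0, y0, x1, y1)
    cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
  hexagon <- function(cx, cy, r) {
    a <- seq(0, 2 * pi, length.out = 7)[-7]
    cbind(x = cx + r * cos(a), y = cy + r * sin(a))
  }
  regions <- list(
    "PrL"     = box(0.05 * w, 0.05 * h, 0.30 * w, 0.25 * h),
    "aCg/M2"  = box(0.35 * w, 0.05 * h, 0.65 * w, 0.25 * h),
    "FPx"     = box(0.70 * w, 0.05 * h, 0.95 * w, 0.25 * h),
    "aDS"     = box(0.05 * w, 0.32 * h, 0.30 * w, 0.60 * h),
    "DMS"     = box(0.35 * w, 0.32 * h, 0.65 * w, 0.60 * h),
    "DLS"     = box(0.70 * w, 0.32 * h, 0.95 * w, 0.60 * h),
    "Core"    = hexagon(0.25 * w, 0.80 * h, 0.12 * h),
    "Shell"   = hexagon(0.65 * w, 0.80 * h, 0.14 * h))
  region_atlas(level, pixel_size_um, regions)
}

#' Generate a synthetic section image with planted somata
#'
#' Plants somata inside each atlas region at a stated expected density
#' (Poisson counts, uniform positions within the polygon), renders each as
#' an isotropic Gaussian intensity blob, and adds Gaussian background
#' noise. The planted ground truth is returned for validation.
#'
#' @param atlas A [region_atlas()].
#' @param per_region_density Named numeric vector: expected somata per
#'   mm^2 for each region (unnamed scalar recycles to all regions).
#' @param soma_radius_px Gaussian blob sigma in pixels.
#' @param intensity Peak blob intensity (image is clipped to `[0, 1]`).
#' @param noise_sd Background noise SD.
#' @param seed Integer seed.
#' @param width,height Image size in pixels.
#' @return List with `image` (matrix indexed `[x + 1, y + 1]`) and `truth`
#'   (data frame `x`, `y`, `region`).
#' @export
generate_section_image <- function(atlas, per_region_density = 40,
                                   soma_radius_px = 3, intensity = 0.8,
                                   noise_sd = 0.03, seed = 1L,
                                   width = 600, height = 400) {
  stopifnot(inherits(atlas, "region_atlas"))
  dens <- per_region_density
  if (is.null(names(dens)))
    dens <- stats::setNames(rep(dens, length.out = length(atlas$regions)),
                            names(atlas$regions))
  if (any(dens < 0)) stop("densities must be >= 0")
  px_mm2 <- (atlas$pixel_size_um / 1000)^2
  with_seed(seed, {
    xs <- ys <- numeric(0); rg <- character(0)
    for (nm in names(atlas$regions)) {
      v <- atlas$regions[[nm]]
      area_mm2 <- polygon_area_px2(v) * px_mm2
      n <- stats::rpois(1, dens[[nm]] * area_mm2)
      if (n == 0) next
      # uniform placement via rejection sampling in the bounding box
      got <- 0
      bx <- range(v[, 1]); by <- range(v[, 2])
      while (got < n) {
        m <- (n - got) * 3 + 8
        cx <- stats::runif(m, bx[1], bx[2])
        cy <- stats::runif(m, by[1], by[2])
        ok <- point_in_polygon(cx, cy, v)
        take <- which(ok)[seq_len(min(n - got, sum(ok)))]
        xs <- c(xs, cx[take]); ys <- c(ys, cy[take])
        rg <- c(rg, rep(nm, length(take)))
        got <- got + length(take)
      }
    }
    img <- matrix(stats::rnorm(width * height, sd = noise_sd), width, height)
    half <- ceiling(4 * soma_radius_px)
    for (k in seq_along(xs)) {
      i0 <- max(1, round(xs[k]) + 1 - half); i1 <- min(width, round(xs[k]) + 1 + half)
      j0 <- max(1, round(ys[k]) + 1 - half); j1 <- min(height, round(ys[k]) + 1 + half)
      gi <- i0:i1; gj <- j0:j1
      blob <- intensity *
        exp(-outer((gi - 1 - xs[k])^2, (gj - 1 - ys[k])^2, "+") /
              (2 * soma_radius_px^2))
      img[gi, gj] <- img[gi, gj] + blob
    }
    img <- pmin(pmax(img, 0), 1)  # img first: pmax/pmin keep its dim attribute
    list(image = img,
         truth = data.frame(x = xs, y = ys, region = rg,
                            stringsAsFactors = FALSE))
  })
}

# Merge 4-connected labels that touch diagonally into 8-connected
# components (union-find over the label ids).
merge_diagonal_labels <- function(L) {
  nl <- max(L)
  if (nl == 0) return(L)
  parent <- seq_len(nl)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  nr <- nrow(L); nc <- ncol(L)
  pairs <- rbind(
    cbind(as.vector(L[-nr, -nc]), as.vector(L[-1, -1])),
    cbind(as.vector(L[-1, -nc]), as.vector(L[-nr, -1])))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs)) {
    pairs <- unique(pairs)
    for (k in seq_len(nrow(pairs))) union(pairs[k, 1], pairs[k, 2])
  }
  root <- vapply(seq_len(nl), find, 0L)
  # compact root ids to 1..n
  map <- stats::setNames(match(root, sort(unique(root))), NULL)
  out <- L
  out[L > 0] <- map[L[L > 0]]
  out
}

#' Detect labelled somata on a section image
#'
#' Particle analysis in the style of thresholded soma counting: a global
#' threshold (Otsu's method by default, or a fixed level), 8-connected
#' component labelling, an area filter, and intensity-weighted centroids.
#'
#' @param image Grayscale image matrix indexed `[x + 1, y + 1]`, values
#'   in `[0, 1]`.
#' @param threshold_mode `"otsu"` or a fixed numeric level inside the
#'   image intensity range.
#' @param min_area_px2,max_area_px2 Component area bounds in pixels^2.
#' @return Data frame of detections: `centroid_x`, `centroid_y` (0-based
#'   pixel coordinates), `area_px2`, `mean_intensity`.
#' @export
detect_somata <- function(image, threshold_mode = "otsu",
                          min_area_px2 = 4, max_area_px2 = Inf) {
  if (length(image) == 0) stop("empty image")
  thr <- if (identical(threshold_mode, "otsu")) {
    EBImage::otsu(EBImage::Image(image), range = c(0, 1))
  } else {
    if (!is.numeric(threshold_mode)) stop("threshold_mode must be 'otsu' or numeric")
    if (threshold_mode < min(image) || threshold_mode > max(image))
      stop("fixed threshold outside the image intensity range")
    threshold_mode
  }
  mask <- image > thr
  if (!any(mask))
    return(data.frame(centroid_x = numeric(0), centroid_y = numeric(0),
                      area_px2 = numeric(0), mean_intensity = numeric(0)))
  L <- merge_diagonal_labels(EBImage::imageData(
    EBImage::bwlabel(EBImage::Image(mask * 1))))
  idx <- which(L > 0)
  lab <- factor(L[idx], levels = seq_len(max(L)))  # keep numeric label order
  xs <- (idx - 1) %% nrow(image)        # 0-based x (row index)
  ys <- (idx - 1) %/% nrow(image)       # 0-based y (column index)
  w <- image[idx]
  area <- tabulate(lab)
  sw <- vapply(split(w, lab), sum, 0)
  cx <- vapply(split(w * xs, lab), sum, 0) / sw
  cy <- vapply(split(w * ys, lab), sum, 0) / sw
  mi <- sw / area
  keep <- area >= min_area_px2 & area <= max_area_px2
  out <- data.frame(centroid_x = cx[keep], centroid_y = cy[keep],
                    area_px2 = area[keep], mean_intensity = mi[keep])
  out <- out[order(out$centroid_x, out$centroid_y), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign detections to atlas regions
#'
#' Each centroid is assigned to the polygon containing it (boundary
#' inclusive). Centroids outside every polygon are `"UNASSIGNED"`; when
#' polygons overlap, the first region in atlas order wins and a warning is
#' issued.
#'
#' @param detections Detection data frame from [detect_somata()].
#' @param atlas A [region_atlas()].
#' @return The detections with an added `region` column.
#' @export
assign_regions <- function(detections, atlas) {
  stopifnot(inherits(atlas, "region_atlas"))
  n <- nrow(detections)
  memb <- vapply(atlas$regions, function(v)
    point_in_polygon(detections$centroid_x, detections$centroid_y, v),
    logical(n))
  if (n == 1) memb <- matrix(memb, nrow = 1)
  hits <- rowSums(memb)
  if (any(hits > 1))
    warning(sum(hits > 1),
            " detection(s) inside overlapping regions; first in atlas order wins")
  first <- apply(memb, 1, function(r) which(r)[1])
  detections$region <- ifelse(hits >= 1, names(atlas$regions)[first],
                              "UNASSIGNED")
  detections
}

#' Regional activation counts and densities for one animal
#'
#' @param detections Region-labelled detections from [assign_regions()].
#' @param atlas A [region_atlas()].
#' @return Data frame with one row per atlas region (plus `UNASSIGNED`):
#'   `region`, `count`, `area_mm2` (shoelace area scaled by the pixel
#'   size; `NA` for unassigned), `density_per_mm2`.
#' @export
region_counts <- function(detections, atlas) {
  stopifnot(inherits(atlas, "region_atlas"))
  px_mm2 <- (atlas$pixel_size_um / 1000)^2
  nm <- names(atlas$regions)
  counts <- table(factor(detections$region, levels = c(nm, "UNASSIGNED")))
  area <- c(vapply(atlas$regions, polygon_area_px2, 0) * px_mm2, NA_real_)
  data.frame(region = c(nm, "UNASSIGNED"),
             count = as.integer(counts),
             area_mm2 = unname(area),
             density_per_mm2 = as.integer(counts) / unname(area),
             stringsAsFactors = FALSE)
}

# Pearson r and two-sided p (t transform, n - 2 df) for all column pairs
# of x against columns of y. Constant columns give NA.
cor_with_p <- function(x, y = x) {
  x <- as.matrix(x); y <- as.matrix(y)
  n <- nrow(x)
  if (n < 3) stop("need at least 3 observations (animals)")
  r <- suppressWarnings(stats::cor(x, y))
  r[!is.finite(r)] <- NA
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[is.na(r)] <- NA
  list(r = r, p = p, n = n)
}

#' Region-by-region cross-correlation of activation counts
#'
#' Correlates the activation level of each region with every other region
#' across animals (Pearson r; two-sided p from the t transform with n - 2
#' degrees of freedom). The r matrix is symmetric with unit diagonal.
#' P-values are reported raw by default, mirroring the per-pair
#' correlation diagrams; Benjamini-Hochberg adjustment of the
#' off-diagonal p-values is available.
#'
#' @param table Animals x regions matrix or data frame of counts (or
#'   densities).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return List with `r`, `p` matrices and `n` (animals).
#' @export
cross_correlation_matrix <- function(table, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  out <- cor_with_p(table)
  diag(out$r) <- 1
  diag(out$p) <- NA
  if (adjust == "BH") {
    up <- upper.tri(out$p)
    out$p[up] <- stats::p.adjust(out$p[up], "BH")
    out$p[lower.tri(out$p)] <- t(out$p)[lower.tri(out$p)]
  }
  out
}

#' Activity-performance correlations
#'
#' Correlates per-animal regional activation counts with per-animal
#' behavioural features (sequence length, duration, speed, total lever
#' presses, ...). A constant feature has undefined correlation and is
#' reported as `NA`.
#'
#' @param region_table Animals x regions matrix/data frame of counts.
#' @param features Animals x features matrix/data frame.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return List with `r`, `p` (regions x features) and `n`.
#' @export
activity_performance_correlation <- function(region_table, features,
                                             adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (nrow(as.matrix(region_table)) != nrow(as.matrix(features)))
    stop("region_table and features must describe the same animals")
  out <- cor_with_p(region_table, features)
  if (adjust == "BH")
    out$p[] <- stats::p.adjust(out$p, "BH")
  out
}

#' Digitised reconstruction of a mapped section
#'
#' Combines the region outlines (closed polylines) with the detected soma
#' centroids (points tagged by region) into a serialisable geometry
#' object.
#'
#' @param detections Region-labelled detections.
#' @param atlas A [region_atlas()].
#' @return A `section_map` list: `level`, `pixel_size_um`, `outlines`
#'   (named list of closed vertex matrices) and `points` (data frame `x`,
#'   `y`, `region`).
#' @export
reconstruct_map <- function(detections, atlas) {
  stopifnot(inherits(atlas, "region_atlas"))
  outlines <- lapply(atlas$regions, function(v) rbind(v, v[1, , drop = FALSE]))
  structure(list(level = atlas$level, pixel_size_um = atlas$pixel_size_um,
                 outlines = outlines,
                 points = data.frame(x = detections$centroid_x,
                                     y = detections$centroid_y,
                                     region = detections$region,
                                     stringsAsFactors = FALSE)),
            class = "section_map")
}

#' Export a section map as GeoJSON-style geometry
#'
#' Region outlines become `Polygon` features and detections become
#' `Point` features with a `region` property.
#'
#' @param map A `section_map` from [reconstruct_map()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_map_geojson <- function(map, path) {
  stopifnot(inherits(map, "section_map"))
  feats <- c(
    lapply(names(map$outlines), function(nm) {
      v <- map$outlines[[nm]]
      list(type = "Feature",
           properties = list(kind = "region", name = nm),
           geometry = list(type = "Polygon",
                           coordinates = list(lapply(seq_len(nrow(v)),
                             function(i) unname(v[i, ])))))
    }),
    lapply(seq_len(nrow(map$points)), function(i) {
      list(type = "Feature",
           properties = list(kind = "soma", region = map$points$region[i]),
           geometry = list(type = "Point",
                           coordinates = c(map$points$x[i], map$points$y[i])))
    }))
  obj <- list(type = "FeatureCollection",
              properties = list(level = map$level,
                                pixel_size_um = map$pixel_size_um),
              features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a section map written by [write_map_geojson()]
#'
#' @param path GeoJSON path.
#' @return A `section_map`.
#' @export
read_map_geojson <- function(path) {
  obj <- jsonlite::read_json(path)
  outlines <- list(); xs <- ys <- numeric(0); rg <- character(0)
  for (f in obj$features) {
    if (f$properties$kind == "region") {
      ring <- f$geometry$coordinates[[1]]
      v <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
      colnames(v) <- c("x", "y")
      outlines[[f$properties$name]] <- v
    } else {
      xs <- c(xs, f$geometry$coordinates[[1]])
      ys <- c(ys, f$geometry$coordinates[[2]])
      rg <- c(rg, f$properties$region)
    }
  }
  structure(list(level = obj$properties$level,
                 pixel_size_um = obj$properties$pixel_size_um,
                 outlines = outlines,
                 points = data.frame(x = xs, y = ys, region = rg,
                                     stringsAsFactors = FALSE)),
            class = "section_map")
}

#' Write an atlas as JSON
#'
#' @param atlas A [region_atlas()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_atlas_json <- function(atlas, path) {
  stopifnot(inherits(atlas, "region_atlas"))
  obj <- list(level = atlas$level, pixel_size_um = atlas$pixel_size_um,
              regions = lapply(names(atlas$regions), function(nm)
                list(name = nm,
                     vertices = lapply(seq_len(nrow(atlas$regions[[nm]])),
                       function(i) unname(atlas$regions[[nm]][i, ])))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an atlas from JSON
#'
#' @param path Atlas JSON path (`{level, pixel_size_um, regions:
#'   [{name, vertices: [[x, y], ...]}]}`).
#' @return A [region_atlas()].
#' @export
read_atlas_json <- function(path) {
  obj <- jsonlite::read_json(path)
  regions <- stats::setNames(
    lapply(obj$regions, function(r)
      do.call(rbind, lapply(r$vertices, function(p) c(x = p[[1]], y = p[[2]])))),
    vapply(obj$regions, function(r) r$name, ""))
  region_atlas(obj$level, obj$pixel_size_um, regions)
}

#' Write a section image as single-channel TIFF
#'
#' @param image Image matrix indexed `[x + 1, y + 1]`, values in `[0, 1]`.
#' @param path Output path.
#' @param bits 8 or 16 bits per sample.
#' @return Invisibly, `path`.
#' @export
write_section_tiff <- function(image, path, bits = 16) {
  tiff::writeTIFF(t(image), path, bits.per.sample = bits)
  invisible(path)
}

#' Read a single-channel TIFF section image
#'
#' @param path TIFF path.
#' @return Image matrix indexed `[x + 1, y + 1]`.
#' @export
read_section_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  t(m)
}
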