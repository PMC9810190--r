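#' Specify a synthetic grain scene
#'
#' Builds a [SceneSpec-class] describing a reproducible synthetic
#' photograph of rice grains on a near-black background: yellow
#' elliptical grains (clipped-feature core, darker shadow rim), optional
#' touching clusters, white elliptical germ protrusions attached with a
#' small contact ratio, and detached white reflection blobs. Defaults
#' emulate the acquisition protocol the pipeline targets: a dark
#' container photographed from above, rice-like grain aspect ratio of
#' about 2.7:1, rim shadows whose red level (around 85) sits well below
#' the grain core (around 225).
#'
#' @param seed RNG seed; the scene is bit-identical for a fixed spec.
#' @param nGrains number of grains.
#' @param grainAxes grain ellipse semi-axes in pixels.
#' @param areaJitter relative jitter on the grain area (0.1 = +/-10\%);
#'   both semi-axes are scaled by the square root of the drawn factor.
#' @param adhesionFraction fraction of grains placed in touching
#'   clusters.
#' @param clusterSizes admissible cluster multiplicities.
#' @param germinationFraction fraction of grains that carry a germ.
#' @param germAxes germ ellipse semi-axes in pixels; the default area
#'   (about s0/5 of the grain core) lies inside the detection window
#'   (s_opt/50, s_opt/3).
#' @param borderShadowWidth width of the darkened rim in pixels.
#' @param shadowRed,coreRed mean red level of rim and core.
#' @param noiseReflections number of detached white blobs (rejected by
#'   the adjacency rule).
#' @param noiseDroplets number of white droplet blobs attached to grain
#'   edges (the documented false-germ error source; default 0).
#' @param noiseSpecks number of tiny grain-colored specks (dust/debris
#'   noise regions, as real photographs carry; they populate the
#'   near-zero start of the area curve that the point-A scan expects).
#' @param backgroundLevel background RGB.
#' @param noiseSd sd of the Gaussian pixel noise added everywhere.
#' @param imageSize optional \code{c(height, width)}; by default the
#'   canvas is sized to hold the requested scene.
#' @param scale linear scale factor applied to all geometry.
#' @param antialias render at 2x and average down (soft edges).
#' @return a [SceneSpec-class] object.
#' @export
sceneSpec <- function(seed = 1L, nGrains = 40L, grainAxes = c(24, 9),
                      areaJitter = 0.1, adhesionFraction = 0.3,
                      clusterSizes = 2:4, germinationFraction = 0.7,
                      germAxes = c(10, 3.5), borderShadowWidth = 2,
                      shadowRed = 85, coreRed = 225,
                      noiseReflections = 3L, noiseDroplets = 0L,
                      noiseSpecks = 5L, backgroundLevel = c(12, 12, 12),
                      noiseSd = 3, imageSize = NULL, scale = 1,
                      antialias = FALSE) {
  new("SceneSpec", seed = as.integer(seed), nGrains = as.integer(nGrains),
      grainAxes = as.numeric(grainAxes), areaJitter = areaJitter,
      adhesionFraction = adhesionFraction,
      clusterSizes = as.integer(clusterSizes),
      germinationFraction = germinationFraction,
      germAxes = as.numeric(germAxes),
      borderShadowWidth = borderShadowWidth, shadowRed = shadowRed,
      coreRed = coreRed, noiseReflections = as.integer(noiseReflections),
      noiseDroplets = as.integer(noiseDroplets),
      noiseSpecks = as.integer(noiseSpecks),
      backgroundLevel = as.numeric(backgroundLevel), noiseSd = noiseSd,
      imageSize = if (is.null(imageSize)) integer(0)
                  else as.integer(imageSize),
      scale = scale, antialias = isTRUE(antialias))
}

# ellipse membership over a bounding box; returns index vector into the
# canvas matrix
ellipsePixels <- function(nr, nc, cx, cy, a, b, theta) {
  r0 <- max(1L, floor(cy - a)); r1 <- min(nr, ceiling(cy + a))
  c0 <- max(1L, floor(cx - a)); c1 <- min(nc, ceiling(cx + a))
  if (r0 > r1 || c0 > c1) return(integer(0))
  rows <- r0:r1; cols <- c0:c1
  dy <- rows - cy
  dx <- cols - cx
  ct <- cos(theta); st <- sin(theta)
  u <- outer(dy, dx, function(y, x) (x * ct + y * st) / a)
  v <- outer(dy, dx, function(y, x) (-x * st + y * ct) / b)
  inside <- which(u^2 + v^2 <= 1)
  ri <- rows[(inside - 1L) %% length(rows) + 1L]
  ci <- cols[(inside - 1L) %/% length(rows) + 1L]
  ri + (ci - 1L) * nr
}

erodeMask <- function(m, width) {
  w <- as.integer(round(width))
  if (w <= 0L) return(m)
  nr <- nrow(m); nc <- ncol(m)
  for (it in seq_len(w)) {
    p <- matrix(FALSE, nr + 2L, nc + 2L)
    p[2:(nr + 1L), 2:(nc + 1L)] <- m
    m <- p[2:(nr + 1L), 2:(nc + 1L)] &
         p[1:nr, 2:(nc + 1L)] & p[3:(nr + 2L), 2:(nc + 1L)] &
         p[2:(nr + 1L), 1:nc] & p[2:(nr + 1L), 3:(nc + 2L)]
  }
  m
}

dilateMask <- function(m, width) {
  w <- as.integer(round(width))
  if (w <= 0L) return(m)
  nr <- nrow(m); nc <- ncol(m)
  for (it in seq_len(w)) {
    p <- matrix(FALSE, nr + 2L, nc + 2L)
    p[2:(nr + 1L), 2:(nc + 1L)] <- m
    m <- p[2:(nr + 1L), 2:(nc + 1L)] |
         p[1:nr, 2:(nc + 1L)] | p[3:(nr + 2L), 2:(nc + 1L)] |
         p[2:(nr + 1L), 1:nc] | p[2:(nr + 1L), 3:(nc + 2L)]
  }
  m
}

clamp255 <- function(x) {
  x[x < 0] <- 0
  x[x > 255] <- 255
  x
}

# Render a scene from explicit placements. `grains` and `germs` are
# data.frames of ellipse parameters (cx, cy, a, b, theta, id); `white`
# holds detached or attached blobs that look like germs but are not.
renderScene <- function(nr, nc, grains, germs, white, spec, sc) {
  grainLab <- matrix(0L, nr, nc)
  for (i in seq_len(nrow(grains))) {
    px <- ellipsePixels(nr, nc, grains$cx[i], grains$cy[i], grains$a[i],
                        grains$b[i], grains$theta[i])
    px <- px[grainLab[px] == 0L]
    grainLab[px] <- grains$id[i]
  }
  union <- grainLab > 0L
  germLab <- matrix(0L, nr, nc)
  if (nrow(germs)) {
    for (i in seq_len(nrow(germs))) {
      px <- ellipsePixels(nr, nc, germs$cx[i], germs$cy[i], germs$a[i],
                          germs$b[i], germs$theta[i])
      px <- px[!union[px] & germLab[px] == 0L]
      germLab[px] <- germs$id[i]
    }
  }
  whiteMask <- matrix(FALSE, nr, nc)
  if (nrow(white)) {
    for (i in seq_len(nrow(white))) {
      px <- ellipsePixels(nr, nc, white$cx[i], white$cy[i], white$a[i],
                          white$b[i], white$theta[i])
      whiteMask[px[!union[px]]] <- TRUE
    }
  }

  # every grain carries its own shadow rim (crevices between touching
  # grains are shadowed too): the bright core of each grain is the same
  # ellipse with both semi-axes reduced by the rim width. Where a germ
  # (or an attached white blob) emerges there is no shadow, so the rim
  # is carved out around bright regions and the core color runs up to
  # the boundary.
  w <- spec@borderShadowWidth * sc
  core <- matrix(FALSE, nr, nc)
  for (i in seq_len(nrow(grains))) {
    px <- ellipsePixels(nr, nc, grains$cx[i], grains$cy[i],
                        max(grains$a[i] - w, 1), max(grains$b[i] - w, 1),
                        grains$theta[i])
    core[px] <- TRUE
  }
  bright <- (germLab > 0L) | whiteMask
  rim <- union & !core & !dilateMask(bright, w + 1)
  core <- union & !rim

  R <- matrix(spec@backgroundLevel[1], nr, nc)
  G <- matrix(spec@backgroundLevel[2], nr, nc)
  B <- matrix(spec@backgroundLevel[3], nr, nc)
  nCore <- sum(core)
  if (nCore) {
    r <- clamp255(stats::rnorm(nCore, spec@coreRed, 10))
    r[r < 180] <- 180
    R[core] <- r
    G[core] <- clamp255(r - 40 + stats::rnorm(nCore, 0, 4))
    B[core] <- pmax(0, r - 155 + stats::rnorm(nCore, 0, 4))
  }
  nRim <- sum(rim)
  if (nRim) {
    r <- stats::rnorm(nRim, spec@shadowRed, 6)
    r[r < 65] <- 65; r[r > 110] <- 110
    R[rim] <- r
    G[rim] <- pmax(0, r - 15)
    B[rim] <- pmax(0, r - 45)
  }
  nW <- sum(bright)
  if (nW) {
    w <- stats::rnorm(nW, 235, 5)
    w[w < 215] <- 215
    w <- clamp255(w)
    R[bright] <- w; G[bright] <- w; B[bright] <- w
  }

  img <- array(0, dim = c(nr, nc, 3L))
  img[, , 1] <- R; img[, , 2] <- G; img[, , 3] <- B
  img <- img + array(stats::rnorm(length(img), 0, spec@noiseSd),
                     dim = dim(img))
  img <- clamp255(floor(img + 0.5))
  storage.mode(img) <- "integer"
  list(image = img, grainLab = grainLab, germLab = germLab)
}

downsample2 <- function(m, f = function(a, b, c, d) (a + b + c + d) / 4) {
  nr <- nrow(m) %/% 2L; nc <- ncol(m) %/% 2L
  i <- seq_len(nr) * 2L; j <- seq_len(nc) * 2L
  f(m[i - 1L, j - 1L, drop = FALSE], m[i - 1L, j, drop = FALSE],
    m[i, j - 1L, drop = FALSE], m[i, j, drop = FALSE])
}

#' Generate a synthetic grain scene with ground truth
#'
#' Lays the requested grains, clusters, germs and noise blobs out on a
#' jittered grid of non-overlapping cells (deterministic for a fixed
#' seed), renders the image, and returns it together with a
#' [GroundTruth-class] object carrying the true counts and per-pixel
#' grain/germ identity.
#'
#' @param spec a [SceneSpec-class] from [sceneSpec()].
#' @return list with \code{image} (integer RGB array), \code{truth}
#'   (a [GroundTruth-class]) and \code{spec}.
#' @examples
#' scene <- generateScene(sceneSpec(seed = 3, nGrains = 6))
#' nGrains(scene$truth)
#' @export
generateScene <- function(spec) {
  validObject(spec)
  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(oldSeed)) assign(".Random.seed", oldSeed,
                                  envir = globalenv())
  })
  set.seed(spec@seed)

  sc <- spec@scale * (if (spec@antialias) 2 else 1)
  n <- spec@nGrains
  jit <- spec@areaJitter
  aG <- spec@grainAxes[1] * sc; bG <- spec@grainAxes[2] * sc
  aB <- spec@germAxes[1] * sc; bB <- spec@germAxes[2] * sc
  germOverlap <- 3 * sc

  # partition grains into clusters and singles
  nAdh <- round(spec@adhesionFraction * n)
  sizes <- integer(0)
  while (sum(sizes) < nAdh) {
    budget <- nAdh - sum(sizes)
    cs <- spec@clusterSizes[sample.int(length(spec@clusterSizes), 1L)]
    cs <- min(cs, max(budget, 2L), n - sum(sizes))
    if (cs < 2L) break
    sizes <- c(sizes, cs)
  }
  multiplicity <- c(sizes, rep(1L, n - sum(sizes)))
  nUnits <- length(multiplicity)

  # cell geometry: every unit (cluster, single, or noise blob) gets one
  # grid cell large enough for the biggest cluster plus germ tips
  maxMult <- max(multiplicity)
  germTip <- 2 * aB * (1 + jit)
  halfStack <- (maxMult - 1) * bG * (1 + jit) + bG * (1 + jit)
  unitR <- aG * (1 + jit) + germTip + spec@borderShadowWidth * sc + 4 * sc
  maxR <- sqrt(unitR^2 + halfStack^2)
  cell <- ceiling(2 * maxR + 2)
  nNoise <- spec@noiseReflections + spec@noiseSpecks
  nCells <- nUnits + nNoise
  if (length(spec@imageSize) == 2L) {
    fac <- if (spec@antialias) 2L else 1L
    nr <- as.integer(spec@imageSize[1]) * fac
    nc <- as.integer(spec@imageSize[2]) * fac
    gx <- nc %/% cell; gy <- nr %/% cell
    if (gx * gy < nCells)
      stop("cannot place ", n, " grains (", nCells, " cells of ", cell,
           " px) in a ", spec@imageSize[1], "x", spec@imageSize[2],
           " image")
  } else {
    gx <- ceiling(sqrt(nCells))
    gy <- ceiling(nCells / gx)
    nc <- as.integer(gx * cell + 2)
    nr <- as.integer(gy * cell + 2)
  }
  cellOrder <- sample(gx * gy, nCells)
  cellCenter <- function(k) {
    cy <- ((k - 1L) %/% gx) * cell + cell / 2 + 1
    cx <- ((k - 1L) %% gx) * cell + cell / 2 + 1
    c(cx, cy)
  }

  germinated <- sort(sample(n, round(spec@germinationFraction * n)))
  grains <- data.frame()
  germs <- data.frame()
  white <- data.frame()
  clusters <- data.frame(clusterId = seq_len(nUnits),
                         multiplicity = multiplicity)
  gid <- 0L
  for (u in seq_len(nUnits)) {
    ctr <- cellCenter(cellOrder[u])
    slack <- max(0, cell / 2 - maxR - 1)
    ctr <- ctr + stats::runif(2, -slack, slack)
    theta <- stats::runif(1, 0, pi)
    mult <- multiplicity[u]
    fj <- sqrt(1 + stats::runif(mult, -jit, jit))  # per-grain area factor
    aj <- aG * fj
    bj <- bG * fj
    # stack cluster members along the minor axis, deep enough that the
    # bright cores (semi-axes reduced by the rim width) still touch
    # after the shadow rims are removed
    offsets <- numeric(mult)
    if (mult > 1L) {
      steps <- (bj[-mult] + bj[-1]) - (2 * spec@borderShadowWidth + 2) * sc
      offsets <- c(0, cumsum(steps))
      offsets <- offsets - mean(offsets)
    }
    perp <- c(-sin(theta), cos(theta))  # minor-axis direction (dx, dy)
    dirM <- c(cos(theta), sin(theta))   # major-axis direction
    for (k in seq_len(mult)) {
      gid <- gid + 1L
      cx <- ctr[1] + perp[1] * offsets[k]
      cy <- ctr[2] + perp[2] * offsets[k]
      grains <- rbind(grains, data.frame(
        cx = cx, cy = cy, a = aj[k], b = bj[k], theta = theta, id = gid,
        clusterId = u))
      if (gid %in% germinated) {
        sgn <- if (mult > 1L) (if (k %% 2L) 1 else -1)
               else (if (stats::runif(1) < 0.5) 1 else -1)
        fb <- sqrt(1 + stats::runif(1, -jit, jit))
        ab <- aB * fb
        bb <- bB * fb
        dist <- aj[k] + ab - germOverlap
        germs <- rbind(germs, data.frame(
          cx = cx + sgn * dirM[1] * dist, cy = cy + sgn * dirM[2] * dist,
          a = ab, b = bb, theta = theta, id = gid))
      }
    }
  }

  # droplets: white blobs attached to grain rims (false-germ material)
  if (spec@noiseDroplets > 0L && nrow(grains)) {
    pick <- sample(nrow(grains), min(spec@noiseDroplets, nrow(grains)))
    for (i in pick) {
      r <- 3.5 * sc
      dist <- grains$b[i] + r - 1 * sc
      perp <- c(-sin(grains$theta[i]), cos(grains$theta[i]))
      white <- rbind(white, data.frame(
        cx = grains$cx[i] + perp[1] * dist,
        cy = grains$cy[i] + perp[2] * dist,
        a = r, b = r, theta = 0))
    }
  }
  # detached reflections and tiny yellow specks in their own cells
  speckPx <- integer(0)
  if (nNoise > 0L) {
    for (j in seq_len(nNoise)) {
      ctr <- cellCenter(cellOrder[nUnits + j])
      ctr <- ctr + stats::runif(2, -cell / 6, cell / 6)
      if (j <= spec@noiseReflections) {
        r <- stats::runif(1, 3.5, 5.5) * sc
        white <- rbind(white, data.frame(cx = ctr[1], cy = ctr[2],
                                         a = r, b = r, theta = 0))
      } else {
        speckPx <- c(speckPx, list(c(ctr, stats::runif(1, 1, 2) * sc)))
      }
    }
  }

  rendered <- renderScene(nr, nc, grains, germs, white, spec, sc)
  img <- rendered$image

  # paint specks after rendering: core-colored dots
  if (spec@noiseSpecks > 0L) {
    for (s in speckPx) {
      px <- ellipsePixels(nr, nc, s[1], s[2], s[3], s[3], 0)
      for (chan in 1:3) {
        m <- img[, , chan]
        m[px] <- as.integer(c(spec@coreRed, spec@coreRed - 40,
                              spec@coreRed - 155)[chan])
        img[, , chan] <- m
      }
    }
  }

  grainLab <- rendered$grainLab
  germLab <- rendered$germLab
  if (spec@antialias) {
    img2 <- array(0L, dim = c(nrow(img) %/% 2L, ncol(img) %/% 2L, 3L))
    for (chan in 1:3)
      img2[, , chan] <- as.integer(floor(downsample2(img[, , chan]) + 0.5))
    img <- img2
    pickTL <- function(a, b, c, d) a
    grainLab <- downsample2(grainLab, pickTL)
    germLab <- downsample2(germLab, pickTL)
  }

  truth <- new("GroundTruth", nGrains = n,
               nGerminated = length(germinated),
               grainLabels = grainLab, germLabels = germLab,
               clusters = clusters)
  list(image = img, truth = truth, spec = spec)
}

#' Generate a named adversarial scene
#'
#' Reproduces the documented failure modes of the method: a reflective
#' water droplet on a grain edge (counted as a false germ), two
#' intertwined germs merging into one bright component (germs
#' undercounted), a germ hidden beneath its grain (missed), and two
#' heavily overlapping grains (grains undercounted). These scenes are
#' for documenting error directions, not for asserting exact counts.
#'
#' @param kind one of \code{"droplet-on-edge"},
#'   \code{"intertwined-germs"}, \code{"germ-under-grain"},
#'   \code{"overlapping-grains"}.
#' @param seed RNG seed.
#' @return list with \code{image}, \code{truth} and \code{kind}.
#' @export
generateAdversarial <- function(kind, seed = 1L) {
  kinds <- c("droplet-on-edge", "intertwined-germs", "germ-under-grain",
             "overlapping-grains")
  if (!is.character(kind) || length(kind) != 1L || !(kind %in% kinds))
    stop("unknown adversarial scenario: ", paste(kind, collapse = ", "),
         " (expected one of: ", paste(kinds, collapse = ", "), ")")
  base <- sceneSpec(seed = seed, nGrains = 16L, adhesionFraction = 0,
                    germinationFraction = 0.5, noiseReflections = 0L)
  if (kind == "droplet-on-edge") {
    spec <- sceneSpec(seed = seed, nGrains = 16L, adhesionFraction = 0,
                      germinationFraction = 0.5, noiseReflections = 0L,
                      noiseDroplets = 2L)
    out <- generateScene(spec)
    return(list(image = out$image, truth = out$truth, kind = kind))
  }

  out <- generateScene(base)
  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(oldSeed)) assign(".Random.seed", oldSeed,
                                  envir = globalenv())
  })
  set.seed(seed + 1L)
  img <- out$image
  nr <- nrow(img); nc <- ncol(img)
  truth <- out$truth
  spec <- base
  sc <- 1

  if (kind == "intertwined-germs") {
    # two fresh grains whose germs meet tip to tip, merging into one
    # bright component, in a padded strip below the base scene
    pad <- 90L
    img2 <- array(0L, dim = c(nr + pad, nc, 3L))
    for (chan in 1:3) {
      m <- matrix(as.integer(spec@backgroundLevel[chan]), nr + pad, nc)
      m[1:nr, ] <- img[, , chan]
      img2[, , chan] <- m
    }
    cy <- nr + pad / 2
    a <- spec@grainAxes[1]; b <- spec@grainAxes[2]
    ab <- spec@germAxes[1]; bb <- spec@germAxes[2]
    # germ tips overlap by 6 px in the middle of the pair
    gap <- 2 * (a + ab - 3) + 2 * ab - 6
    g1 <- c(nc / 2 - gap / 2, cy); g2 <- c(nc / 2 + gap / 2, cy)
    grains <- data.frame(cx = c(g1[1], g2[1]), cy = cy, a = a, b = b,
                         theta = 0, id = c(98L, 99L), clusterId = 0L)
    germs <- data.frame(
      cx = c(g1[1] + a + ab - 3, g2[1] - a - ab + 3), cy = cy,
      a = ab, b = bb, theta = 0, id = c(98L, 99L))
    piece <- renderScene(nr + pad, nc, grains, germs, data.frame(),
                         spec, sc)
    drawn <- piece$grainLab > 0L | piece$germLab > 0L
    for (chan in 1:3) {
      m <- img2[, , chan]
      m[drawn] <- piece$image[, , chan][drawn]
      img2[, , chan] <- m
    }
    gl <- matrix(0L, nr + pad, nc); gl[1:nr, ] <- truth@grainLabels
    gl[piece$grainLab > 0L] <- piece$grainLab[piece$grainLab > 0L]
    bl <- matrix(0L, nr + pad, nc); bl[1:nr, ] <- truth@germLabels
    bl[piece$germLab > 0L] <- piece$germLab[piece$germLab > 0L]
    truth <- new("GroundTruth", nGrains = truth@nGrains + 2L,
                 nGerminated = truth@nGerminated + 2L,
                 grainLabels = gl, germLabels = bl,
                 clusters = truth@clusters)
    return(list(image = img2, truth = truth, kind = kind))
  }

  if (kind == "germ-under-grain") {
    # give a non-germinated grain a germ that is almost fully hidden:
    # only a sliver shorter than s_opt/50 emerges
    lab <- truth@grainLabels
    germIds <- unique(truth@germLabels[truth@germLabels > 0L])
    hidden <- setdiff(seq_len(truth@nGrains), germIds)[1]
    px <- which(lab == hidden, arr.ind = TRUE)
    cy <- mean(px[, 1]); cx <- mean(px[, 2])
    # a thin white sliver poking 2 px beyond the grain hull
    edge <- px[which.max(px[, 2]), ]
    sl <- ellipsePixels(nr, nc, edge[2] + 1, edge[1], 2.2, 1.2, 0)
    sl <- sl[truth@grainLabels[sl] == 0L]
    for (chan in 1:3) {
      m <- img[, , chan]
      m[sl] <- 235L
      img[, , chan] <- m
    }
    bl <- truth@germLabels
    bl[sl] <- hidden
    truth <- new("GroundTruth", nGrains = truth@nGrains,
                 nGerminated = truth@nGerminated + 1L,
                 grainLabels = truth@grainLabels, germLabels = bl,
                 clusters = truth@clusters)
    return(list(image = img, truth = truth, kind = kind))
  }

  # overlapping-grains: append a pair of grains overlapping by ~60%
  pad <- 90L
  img2 <- array(0L, dim = c(nr + pad, nc, 3L))
  for (chan in 1:3) {
    m <- matrix(as.integer(spec@backgroundLevel[chan]), nr + pad, nc)
    m[1:nr, ] <- img[, , chan]
    img2[, , chan] <- m
  }
  cy <- nr + pad / 2
  a <- spec@grainAxes[1]; b <- spec@grainAxes[2]
  d <- 0.5 * a  # heavy overlap along the major axis
  grains <- data.frame(cx = c(nc / 2 - d / 2, nc / 2 + d / 2), cy = cy,
                       a = a, b = b, theta = 0, id = c(98L, 99L),
                       clusterId = 0L)
  piece <- renderScene(nr + pad, nc, grains, data.frame(), data.frame(),
                       spec, sc)
  drawn <- piece$grainLab > 0L
  for (chan in 1:3) {
    m <- img2[, , chan]
    m[drawn] <- piece$image[, , chan][drawn]
    img2[, , chan] <- m
  }
  gl <- matrix(0L, nr + pad, nc); gl[1:nr, ] <- truth@grainLabels
  gl[drawn] <- piece$grainLab[drawn]
  bl <- matrix(0L, nr + pad, nc); bl[1:nr, ] <- truth@germLabels
  truth <- new("GroundTruth", nGrains = truth@nGrains + 2L,
               nGerminated = truth@nGerminated,
               grainLabels = gl, germLabels = bl,
               clusters = truth@clusters)
  list(image = img2, truth = truth, kind = kind)
}

#' Write a scene image and its ground truth to disk
#'
#' Writes \code{<name>.png} and \code{<name>_truth.json} (fields
#' \code{n_grains}, \code{n_germinated}, \code{germination_rate},
#' \code{clusters}) into a directory, the layout [batchRun()] consumes.
#'
#' @param scene result of [generateScene()] or [generateAdversarial()].
#' @param dir output directory (created if missing).
#' @param name file stem.
#' @return invisibly, the image path.
#' @export
writeScene <- function(scene, dir, name = "scene") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  imgPath <- file.path(dir, paste0(name, ".png"))
  writeRgbImage(scene$image, imgPath)
  truth <- scene$truth
  obj <- list(n_grains = truth@nGrains,
              n_germinated = truth@nGerminated,
              germination_rate = truth@nGerminated / truth@nGrains,
              clusters = truth@clusters)
  jsonlite::write_json(obj, file.path(dir, paste0(name, "_truth.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(imgPath)
}
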