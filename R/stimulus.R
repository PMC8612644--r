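#' Generate synthetic textured oval stimuli
#'
#' Produces grayscale images with controllable class structure: each class
#' has a fixed smooth random texture template, each sample is the template
#' plus pixel noise, rescaled to `[0, 1]` and masked with an oval aperture
#' (outside-aperture pixels are 0). These synthetic stimuli stand in for
#' photographs, which are not redistributable; class separability is
#' controlled by `class_strength`.
#'
#' @param n_per_class Samples per class (default 8).
#' @param n_classes Number of classes (default 5).
#' @param size Image side length in pixels (default 64).
#' @param class_strength Template-to-noise ratio (0 = no class signal).
#' @param seed RNG seed.
#' @return List: `images` (list of size x size matrices in `[0,1]`),
#'   `labels` (factor), `aperture` (logical matrix).
#' @export
generate_stimuli <- function(n_per_class = 8L, n_classes = 5L, size = 64L,
                             class_strength = 1, seed = 1L) {
  xx <- matrix(rep(seq_len(size), size), size)
  yy <- t(xx)
  c0 <- (size + 1) / 2
  aperture <- ((xx - c0) / (0.38 * size))^2 + ((yy - c0) / (0.46 * size))^2 <= 1
  smooth2 <- function(m) {
    k <- 5L
    out <- m
    for (i in 1:2) {
      out <- t(apply(out, 1, function(v) {
        as.numeric(stats::filter(c(rep(v[1], k), v, rep(v[length(v)], k)),
                                 rep(1 / (2 * k + 1), 2 * k + 1),
                                 sides = 2))[(k + 1):(k + length(v))]
      }))
    }
    out
  }
  with_seed(sub_seed(seed, 333L), {
    templates <- lapply(seq_len(n_classes), function(i) {
      smooth2(matrix(rnorm(size^2), size))
    })
    images <- list()
    labels <- integer(0)
    for (cl in seq_len(n_classes)) {
      for (s in seq_len(n_per_class)) {
        im <- class_strength * templates[[cl]] +
          0.2 * matrix(rnorm(size^2), size)
        im <- (im - min(im)) / (max(im) - min(im))
        im[!aperture] <- 0
        images[[length(images) + 1L]] <- im
        labels <- c(labels, cl)
      }
    }
    list(images = images,
         labels = factor(paste0("class", labels)),
         aperture = aperture)
  })
}

#' Radially averaged power spectrum of an image
#'
#' @param image 2-D numeric matrix.
#' @return Tibble: `freq` (integer radial frequency bin), `power` (mean
#'   squared Fourier amplitude in the bin).
#' @export
radial_power <- function(image) {
  f <- fft(image)
  p <- Mod(f)^2
  n <- dim(image)
  fx <- c(0:(n[1] %/% 2), -((n[1] - n[1] %/% 2 - 1):1))
  fy <- c(0:(n[2] %/% 2), -((n[2] - n[2] %/% 2 - 1):1))
  r <- round(sqrt(outer(fx^2, fy^2, "+")))
  tibble::tibble(
    freq = sort(unique(as.vector(r))),
    power = as.numeric(tapply(as.vector(p), as.vector(r), mean))
  )
}

#' Equalize luminance histograms and power spectra across images
#'
#' Iteratively imposes (a) the set-average luminance histogram on every
#' image by rank matching and (b) the set-average Fourier amplitude spectrum
#' while retaining each image's own phase. Each round runs the histogram
#' step then the spectrum step, so after the final round all images share
#' the amplitude spectrum exactly.
#'
#' @param images List of equally sized 2-D matrices.
#' @param rounds Iteration count (default 3).
#' @return List of equalized images.
#' @export
equalize_images <- function(images, rounds = 3L) {
  dims <- lapply(images, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L) {
    stop("all images must have identical dimensions", call. = FALSE)
  }
  for (i in seq_len(rounds)) {
    images <- equalize_spectrum_step(equalize_histogram_step(images))
  }
  images
}

# Rank-match every image's luminance histogram to the set average
# (ties broken by index order: deterministic).
equalize_histogram_step <- function(imgs) {
  sorted <- vapply(imgs, function(im) sort(as.vector(im)),
                   numeric(length(imgs[[1]])))
  avg <- rowMeans(sorted)
  lapply(imgs, function(im) {
    v <- as.vector(im)
    v[order(v)] <- avg
    matrix(v, nrow(im))
  })
}

# Impose the set-average Fourier amplitude spectrum, retaining each image's
# own phase exactly.
equalize_spectrum_step <- function(imgs) {
  fs <- lapply(imgs, fft)
  amp <- Reduce(`+`, lapply(fs, Mod)) / length(fs)
  lapply(fs, function(f) {
    ph <- Arg(f)
    Re(fft(amp * complex(modulus = 1, argument = ph), inverse = TRUE)) /
      length(f)
  })
}

# One Gabor filter: size s pixels, orientation theta, zero mean, unit norm.
gabor_filter <- function(s, theta, gamma = 0.3) {
  sigma <- 0.0036 * s^2 + 0.35 * s + 0.18
  lambda <- sigma / 0.8
  half <- (s - 1) / 2
  x <- matrix(rep(seq(-half, half), s), s)
  y <- t(x)
  xr <- x * cos(theta) + y * sin(theta)
  yr <- -x * sin(theta) + y * cos(theta)
  g <- exp(-(xr^2 + gamma^2 * yr^2) / (2 * sigma^2)) * cos(2 * pi * xr / lambda)
  g <- g - mean(g)
  g / sqrt(sum(g^2))
}

# Same-size circular 2-D convolution via FFT with the kernel centred.
conv2_same <- function(im, kern) {
  n <- dim(im)
  kp <- matrix(0, n[1], n[2])
  s <- dim(kern)
  kp[seq_len(s[1]), seq_len(s[2])] <- kern
  # centre the kernel at (1,1) by circular shift
  sh <- floor(s / 2)
  kp <- kp[((seq_len(n[1]) - 1 + sh[1]) %% n[1]) + 1,
           ((seq_len(n[2]) - 1 + sh[2]) %% n[2]) + 1]
  Re(fft(fft(im) * fft(kp), inverse = TRUE)) / length(im)
}

#' Gabor simple/complex (S1/C1) feature extraction
#'
#' Models V1-like responses: S1 maps are the absolute responses of zero-mean
#' unit-norm Gabor filters over `orientations` orientations and the supplied
#' filter sizes; C1 features max-pool S1 over local spatial cells
#' (half-overlapping) and over adjacent-scale pairs, and the pooled values
#' are concatenated into one vector.
#'
#' @param image 2-D numeric matrix.
#' @param orientations Number of orientations (default 4).
#' @param scales Gabor filter sizes in pixels, paired consecutively into C1
#'   bands (default 8 sizes, 7 to 21, giving 4 bands).
#' @param pool_sizes Spatial pooling cell size per band (defaults 8, 10, 12,
#'   14 pixels).
#' @return Numeric feature vector.
#' @export
gabor_c1_features <- function(image, orientations = 4L,
                              scales = seq(7L, 21L, by = 2L),
                              pool_sizes = NULL) {
  if (max(scales) > min(dim(image))) {
    stop("largest filter exceeds image size", call. = FALSE)
  }
  n_bands <- length(scales) %/% 2L
  if (is.null(pool_sizes)) pool_sizes <- 8L + 2L * (seq_len(n_bands) - 1L)
  thetas <- pi * (seq_len(orientations) - 1L) / orientations
  feats <- numeric(0)
  for (b in seq_len(n_bands)) {
    sc <- scales[c(2L * b - 1L, 2L * b)]
    p <- pool_sizes[b]
    step <- max(1L, p %/% 2L)
    xs <- seq(1L, dim(image)[1] - p + 1L, by = step)
    ys <- seq(1L, dim(image)[2] - p + 1L, by = step)
    for (th in thetas) {
      s1 <- pmax(abs(conv2_same(image, gabor_filter(sc[1], th))),
                 abs(conv2_same(image, gabor_filter(sc[2], th))))
      for (ix in xs) for (iy in ys) {
        feats <- c(feats, max(s1[ix:(ix + p - 1L), iy:(iy + p - 1L)]))
      }
    }
  }
  feats
}

#' Multiclass leave-one-sample-out cross-validated classification
#'
#' Folds leave out one sample per class simultaneously (requiring equal
#' class sizes); a linear one-vs-one support-vector classifier is trained on
#' the rest and the confusion matrix accumulated over folds. An optional
#' permutation test re-runs the whole procedure with shuffled labels to
#' estimate the chance distribution.
#'
#' @param features n x p feature matrix.
#' @param labels Length-n class labels (equal class sizes).
#' @param cost SVM cost (default 1).
#' @param n_perm Label permutations for the chance test (default 0 = none).
#' @param seed Permutation seed.
#' @return List: `accuracy`, `confusion` (expected x predicted counts),
#'   `per_class_tpr`, `perm_accuracies`, `perm_p` (add-one convention; NULL
#'   without permutations).
#' @export
multiclass_loocv <- function(features, labels, cost = 1, n_perm = 0L,
                             seed = 1L) {
  labels <- factor(labels)
  sizes <- table(labels)
  if (length(unique(sizes)) != 1L) {
    stop("fold construction requires equal class sizes", call. = FALSE)
  }
  n_folds <- unname(sizes[1])
  run_cv <- function(labs) {
    # the fold rule (one sample per class, by within-class order) is part of
    # the procedure and is re-derived from the labels in use, so permutation
    # re-runs keep training folds class-balanced
    fold_of <- integer(length(labs))
    for (cl in levels(labs)) {
      fold_of[labs == cl] <- seq_len(n_folds)
    }
    conf <- matrix(0L, nlevels(labs), nlevels(labs),
                   dimnames = list(expected = levels(labs),
                                   predicted = levels(labs)))
    for (f in seq_len(n_folds)) {
      te <- fold_of == f
      fit <- e1071::svm(features[!te, , drop = FALSE], labs[!te],
                        kernel = "linear", cost = cost, scale = FALSE)
      pred <- stats::predict(fit, features[te, , drop = FALSE])
      for (i in which(te)) {
        conf[as.integer(labs[i]), as.integer(pred[match(i, which(te))])] <-
          conf[as.integer(labs[i]), as.integer(pred[match(i, which(te))])] + 1L
      }
    }
    conf
  }
  conf <- run_cv(labels)
  acc <- sum(diag(conf)) / sum(conf)
  perm_acc <- NULL
  perm_p <- NULL
  if (n_perm > 0L) {
    perm_acc <- with_seed(sub_seed(seed, 77L), {
      vapply(seq_len(n_perm), function(i) {
        cp <- run_cv(sample(labels))
        sum(diag(cp)) / sum(cp)
      }, numeric(1))
    })
    perm_p <- (1 + sum(perm_acc >= acc)) / (1 + n_perm)
  }
  structure(list(
    accuracy = acc,
    confusion = conf,
    per_class_tpr = diag(conf) / rowSums(conf),
    perm_accuracies = perm_acc,
    perm_p = perm_p
  ), class = "loocv_result")
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("<loocv_result> accuracy = %.3f", x$accuracy))
  if (!is.null(x$perm_p)) cat(sprintf(", permutation p = %.4g", x$perm_p))
  cat("\n")
  invisible(x)
}
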