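#' Density-component specification for synthetic nodules
#'
#' Synthetic nodules mix three tissue density classes whose default mean
#' attenuations match the habitat phenotypes seen in invasive pulmonary
#' adenocarcinoma at non-contrast CT: a dense "sub-solid" component near
#' -72.6 HU, an air-like lepidic/alveolar component near -827.25 HU, and an
#' intermediate mixed component near -424.05 HU.
#'
#' @param name one of `"dense"`, `"air_like"`, `"intermediate"`.
#' @param mean_hu,sd_hu sampling distribution of voxel HU for this component.
#' @param target_fraction desired volume fraction in \[0, 1\].
#' @return An object of class `component_spec`.
#' @export
component_spec <- function(name = c("dense", "air_like", "intermediate"),
                           mean_hu, sd_hu, target_fraction) {
  name <- match.arg(name)
  if (sd_hu < 0 || target_fraction < 0 || target_fraction > 1)
    stop_habitat("invalid component spec", "habitat_parameter_error")
  structure(list(name = name, mean_hu = mean_hu, sd_hu = sd_hu,
                 target_fraction = target_fraction), class = "component_spec")
}

#' Default three-component mixtures per grade
#'
#' Fractions are anchored to the published medians of subregion proportions
#' per grade group (high grade: a dominant dense component and a nearly
#' absent air-like component; low grade: intermediate-dominated).
#'
#' @param grade `"low"` or `"high"`.
#' @return A list of three `component_spec`s (dense, air_like, intermediate).
#' @export
default_components <- function(grade = c("low", "high")) {
  grade <- match.arg(grade)
  fr <- if (grade == "high") c(dense = 0.62, air_like = 0.03, intermediate = 0.35)
        else                 c(dense = 0.20, air_like = 0.15, intermediate = 0.65)
  list(
    dense        = component_spec("dense",        -72.6,  60, fr[["dense"]]),
    air_like     = component_spec("air_like",     -827.25, 95, fr[["air_like"]]),
    intermediate = component_spec("intermediate", -424.05, 85, fr[["intermediate"]])
  )
}

validate_components <- function(comps) {
  stopifnot(length(comps) == 3L)
  nm <- vapply(comps, function(c) c$name, "")
  if (!setequal(nm, c("dense", "air_like", "intermediate")))
    stop_habitat("components must be dense, air_like, intermediate", "habitat_parameter_error")
  comps <- comps[match(c("dense", "air_like", "intermediate"), nm)]
  fr <- vapply(comps, function(c) c$target_fraction, 0)
  if (abs(sum(fr) - 1) > 1e-9)
    stop_habitat("component target fractions must sum to 1", "habitat_parameter_error")
  mu <- vapply(comps, function(c) c$mean_hu, 0)
  if (!(mu[1] > mu[3] && mu[3] > mu[2]))
    stop_habitat("component means must satisfy dense > intermediate > air_like",
                 "habitat_parameter_error")
  comps
}

#' Recipe for one synthetic nodule
#'
#' @param grade `"low"` or `"high"`; sets the default component fractions and
#'   the peripheral placement of the air-like component (high-grade nodules
#'   push air-like tissue to the rim, shrinking the dense/air interface).
#' @param diameter_mm nodule diameter (> 0).
#' @param spacing_mm voxel spacing, mm.
#' @param components list of three [component_spec()]s; defaults per grade.
#' @param interface_scale Gaussian smoothing width (mm) of the random fields
#'   that place components; larger values give coarser, more coherent blobs.
#' @param periphery_weight strength of the peripheral bias of the air-like
#'   component (and central bias of the dense one); default 1.5 for
#'   high-grade, 0 for low-grade recipes.
#' @param background_hu HU level outside the lesion (lung parenchyma).
#' @param background_sd HU noise outside the lesion.
#' @param seed integer seed; identical recipes reproduce identical nodules.
#' @return An object of class `nodule_recipe`.
#' @export
nodule_recipe <- function(grade = c("low", "high"), diameter_mm = 18,
                          spacing_mm = c(1, 1, 1),
                          components = default_components(grade),
                          interface_scale = 4,
                          periphery_weight = NULL,
                          background_hu = -850, background_sd = 30,
                          seed = 1L) {
  grade <- match.arg(grade)
  if (diameter_mm <= 0) stop_habitat("diameter must be positive", "habitat_parameter_error")
  if (any(spacing_mm <= 0)) stop_habitat("spacing must be positive", "habitat_parameter_error")
  if (interface_scale <= 0) stop_habitat("interface_scale must be positive", "habitat_parameter_error")
  components <- validate_components(components)
  if (is.null(periphery_weight)) periphery_weight <- if (grade == "high") 1.5 else 0
  structure(list(grade = grade, diameter_mm = diameter_mm,
                 spacing_mm = as.numeric(spacing_mm), components = components,
                 interface_scale = interface_scale,
                 periphery_weight = periphery_weight,
                 background_hu = background_hu, background_sd = background_sd,
                 seed = as.integer(seed)),
            class = "nodule_recipe")
}

# separable Gaussian convolution along one axis (replicate padding)
convolve_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  r <- (length(kernel) - 1L) %/% 2L
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(arr, perm), nrow = d[axis])
  n <- nrow(m)
  pad <- pmin(pmax(seq_len(n + 2L * r) - r, 1L), n)
  mp <- m[pad, , drop = FALSE]
  out <- stats::filter(mp, kernel, sides = 2)
  out <- out[(r + 1L):(r + n), , drop = FALSE]
  aperm(array(out, dim = d[perm]), order(perm))
}

# smooth standard-normal-ish random field; sigma per axis in voxels
smooth_field <- function(dims, sigma_vox) {
  f <- array(rnorm(prod(dims)), dim = dims)
  for (a in 1:3) {
    s <- sigma_vox[a]
    if (s < 0.3) next
    r <- max(1L, ceiling(3 * s))
    k <- dnorm(seq(-r, r) / s)
    k <- k / sum(k)
    f <- convolve_axis(f, k, a)
  }
  f <- f - mean(f)
  sdev <- sd(as.vector(f))
  if (sdev > 0) f <- f / sdev
  f
}

#' Generate one synthetic nodule
#'
#' Builds a roughly ellipsoidal single-connected lesion mask, partitions it
#' into three spatially coherent density components by thresholding smoothed
#' random fields at the exact target fractions, and samples HU values from
#' each component's Gaussian. Outside the mask, voxels sit at a lung
#' background level.
#'
#' @param recipe a [nodule_recipe()].
#' @return `list(volume, mask, truth, component_map)` where `truth` is the
#'   realized per-component voxel fraction (named dense/air_like/intermediate)
#'   and `component_map` codes 0 = background, 1 = dense, 2 = air_like,
#'   3 = intermediate.
#' @export
generate_nodule <- function(recipe) {
  stopifnot(inherits(recipe, "nodule_recipe"))
  sp <- recipe$spacing_mm
  if (any(recipe$diameter_mm / sp < 3))
    stop_habitat("nodule smaller than 3 voxels along an axis", "habitat_degenerate_geometry_error")
  set.seed(recipe$seed)

  r_mm <- recipe$diameter_mm / 2
  semi <- r_mm * runif(3, 0.9, 1.1)
  margin <- 3L
  dims <- as.integer(ceiling(2 * semi * 1.1 / sp) + 2L * margin)
  ctr <- (dims + 1) / 2

  ax <- lapply(1:3, function(a) ((seq_len(dims[a]) - ctr[a]) * sp[a]) / semi[a])
  rho2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
  rho <- sqrt(rho2)

  sig_vox <- pmax(recipe$interface_scale / sp, 0.5)
  surf <- smooth_field(dims, sig_vox * 1.5)
  mask <- rho <= 1 + 0.08 * surf
  # keep the largest 6-connected component so the lesion is single-connected
  cc <- .cc6(as.logical(mask), as.integer(dims))
  if (attr(cc, "n_components") > 1L) {
    keep <- which.max(tabulate(cc[cc > 0L]))
    mask <- array(cc == keep, dim = dims)
  } else mask <- array(mask, dim = dims)
  V <- sum(mask)
  if (V < 30) stop_habitat("mask has fewer than 30 voxels", "habitat_degenerate_geometry_error")

  comps <- recipe$components
  fr <- vapply(comps, function(c) c$target_fraction, 0)
  f1 <- smooth_field(dims, sig_vox)
  f2 <- smooth_field(dims, sig_vox)
  w <- recipe$periphery_weight
  inm <- which(mask)
  rho_in <- rho[inm]

  n_air <- round(fr[["air_like"]] * V)
  n_dense <- round(fr[["dense"]] * V)
  if (n_air + n_dense > V) n_dense <- V - n_air
  comp_in <- rep.int(3L, V)               # intermediate by default
  air_score <- f1[inm] + w * rho_in       # peripheral air in high grade
  air_idx <- order(air_score, decreasing = TRUE)[seq_len(n_air)]
  if (n_air > 0) comp_in[air_idx] <- 2L
  rest <- which(comp_in == 3L)
  dense_score <- f2[inm][rest] - w * rho_in[rest]  # central dense in high grade
  dense_idx <- rest[order(dense_score, decreasing = TRUE)[seq_len(min(n_dense, length(rest)))]]
  if (n_dense > 0) comp_in[dense_idx] <- 1L

  cmap <- array(0L, dim = dims)
  cmap[inm] <- comp_in

  hu <- array(rnorm(prod(dims), recipe$background_hu, recipe$background_sd), dim = dims)
  mu <- c(comps$dense$mean_hu, comps$air_like$mean_hu, comps$intermediate$mean_hu)
  sdv <- c(comps$dense$sd_hu, comps$air_like$sd_hu, comps$intermediate$sd_hu)
  hu[inm] <- rnorm(V, mu[comp_in], sdv[comp_in])

  truth <- c(dense = sum(comp_in == 1L), air_like = sum(comp_in == 2L),
             intermediate = sum(comp_in == 3L)) / V
  list(volume = ct_volume(hu, sp, domain = "HU"),
       mask = lesion_mask(mask, sp),
       truth = truth,
       component_map = cmap)
}

#' Multicenter study cohort layout
#'
#' Per-cohort low/high-grade case counts of the study design the generator
#' emulates: 355 cases across training, validation and independent test
#' cohorts with an overall 18.6% high-grade prevalence.
#'
#' @return data.frame with columns `cohort`, `n_low`, `n_high`.
#' @export
cohort_design <- function() {
  data.frame(cohort = c("training", "validation", "test"),
             n_low = c(129L, 47L, 113L),
             n_high = c(32L, 19L, 15L))
}

#' Recipe for a synthetic cohort
#'
#' @param n_train,n_val,n_test case counts (defaults 161/66/128).
#' @param prevalence_high expected high-grade proportion (default 0.186);
#'   the realized high-grade count per cohort is `round(prevalence * n)`.
#' @param diameter_model per-grade log-normal diameter distribution
#'   (`meanlog`, `sdlog`, truncated to `range`); defaults follow the study's
#'   per-grade tumor-diameter medians and interquartile ranges.
#' @param fraction_jitter_sd log-scale jitter applied to component fractions
#'   per case (case-to-case compositional heterogeneity).
#' @param interface_scale,spacing_mm passed to each nodule recipe.
#' @param seed master seed; child streams derive from it per case and per
#'   purpose, so identical seeds reproduce identical cohorts.
#' @return An object of class `cohort_recipe`.
#' @export
cohort_recipe <- function(n_train = 161L, n_val = 66L, n_test = 128L,
                          prevalence_high = 0.186,
                          diameter_model = list(
                            low = list(meanlog = log(16), sdlog = 0.33, range = c(8, 40)),
                            high = list(meanlog = log(21), sdlog = 0.30, range = c(8, 40))),
                          fraction_jitter_sd = 0.4,
                          interface_scale = 4, spacing_mm = c(1, 1, 1),
                          seed = 1L) {
  if (any(c(n_train, n_val, n_test) <= 0))
    stop_habitat("cohort sizes must be positive", "habitat_parameter_error")
  if (prevalence_high < 0 || prevalence_high >= 1)
    stop_habitat("prevalence must be in [0, 1)", "habitat_parameter_error")
  structure(list(n_train = as.integer(n_train), n_val = as.integer(n_val),
                 n_test = as.integer(n_test), prevalence_high = prevalence_high,
                 diameter_model = diameter_model,
                 fraction_jitter_sd = fraction_jitter_sd,
                 interface_scale = interface_scale,
                 spacing_mm = spacing_mm, seed = as.integer(seed)),
            class = "cohort_recipe")
}

# per-grade marginal covariate distributions, parameterized from the pooled
# per-grade frequencies of the study's baseline table (no correlations).
covariate_model_default <- function() {
  list(
    gender = list(levels = c("male", "female"),
                  low = c(106, 183) / 289, high = c(37, 29) / 66),
    age = list(low = c(mean = 63, sd = 9), high = c(mean = 62, sd = 10)),
    smoking = list(levels = c("long_term", "ever", "never"),
                   low = c(50, 67, 172) / 289, high = c(21, 7, 38) / 66),
    alcohol = list(levels = c("heavy", "light", "never"),
                   low = c(39, 66, 184) / 289, high = c(11, 17, 38) / 66),
    stage = list(levels = c("I", "II", "III"),
                 low = c(221, 44, 24) / 289, high = c(33, 22, 11) / 66),
    lobe = list(levels = c("LUL", "LLL", "RUL", "RML", "RLL"),
                low = c(74, 38, 92, 20, 65) / 289, high = c(16, 15, 22, 4, 9) / 66),
    shape = list(levels = c("round_oval", "irregular"),
                 low = c(19, 270) / 289, high = c(10, 56) / 66),
    attenuation = list(levels = c("solid", "part_solid", "ground_glass"),
                       low = c(106, 141, 42) / 289, high = c(53, 12, 1) / 66),
    lobulation = list(levels = c("yes", "no"),
                      low = c(238, 51) / 289, high = c(63, 3) / 66),
    air_bronchogram = list(levels = c("yes", "no"),
                           low = c(109, 180) / 289, high = c(29, 37) / 66),
    spiculation = list(levels = c("yes", "no"),
                       low = c(156, 133) / 289, high = c(57, 9) / 66),
    pleural_tag = list(levels = c("yes", "no"),
                       low = c(206, 83) / 289, high = c(59, 7) / 66),
    cavity = list(levels = c("yes", "no"),
                  low = c(14, 275) / 289, high = c(3, 63) / 66)
  )
}

sample_cat <- function(n, levels, prob) factor(sample(levels, n, TRUE, prob), levels = levels)

#' Generate a synthetic nodule cohort
#'
#' Draws grade labels and covariates per cohort, builds one synthetic nodule
#' per case, and (optionally) writes image/mask pairs as NIfTI plus a
#' tab-delimited covariate table.
#'
#' @param recipe a [cohort_recipe()].
#' @param out_dir optional output directory; refuses to reuse a non-empty
#'   directory unless `overwrite = TRUE`.
#' @param keep_volumes keep generated volumes in memory (`cases` element);
#'   set `FALSE` to only produce the table (and files, if `out_dir` given).
#' @param overwrite allow writing into an existing non-empty directory.
#' @param images set `FALSE` to skip image synthesis entirely and return the
#'   covariate table alone (fast bookkeeping path).
#' @return `list(table = covariate data.frame, cases = list or NULL)`. Each
#'   case holds the `generate_nodule()` output plus its row id.
#' @export
generate_cohort <- function(recipe, out_dir = NULL, keep_volumes = is.null(out_dir),
                            overwrite = FALSE, images = TRUE) {
  stopifnot(inherits(recipe, "cohort_recipe"))
  if (!is.null(out_dir)) {
    if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !overwrite)
      stop_habitat("output directory exists and is not empty; set overwrite = TRUE",
                   "habitat_output_collision_error")
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  }
  cohorts <- c(training = recipe$n_train, validation = recipe$n_val,
               test = recipe$n_test)
  cov_model <- covariate_model_default()

  set.seed(child_seed(recipe$seed, "assignment"))
  rows <- list()
  for (co in names(cohorts)) {
    n <- cohorts[[co]]
    n_high <- round(recipe$prevalence_high * n)
    grade <- sample(rep(c("high", "low"), c(n_high, n - n_high)))
    rows[[co]] <- data.frame(cohort = co, grade = grade)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  n_all <- nrow(tab)
  tab <- cbind(case_id = sprintf("case_%03d", seq_len(n_all)), tab)

  set.seed(child_seed(recipe$seed, "covariates"))
  g <- tab$grade
  draw <- function(var) {
    out <- character(n_all)
    for (gr in c("low", "high")) {
      i <- which(g == gr)
      out[i] <- as.character(sample_cat(length(i), var$levels, var[[gr]]))
    }
    factor(out, levels = var$levels)
  }
  for (v in setdiff(names(cov_model), "age")) tab[[v]] <- draw(cov_model[[v]])
  age <- numeric(n_all)
  for (gr in c("low", "high")) {
    i <- which(g == gr)
    p <- cov_model$age[[gr]]
    age[i] <- round(pmin(pmax(rnorm(length(i), p[["mean"]], p[["sd"]]), 30), 90))
  }
  tab$age <- age
  diam <- numeric(n_all)
  for (gr in c("low", "high")) {
    i <- which(g == gr)
    p <- recipe$diameter_model[[gr]]
    d <- rlnorm(length(i), p$meanlog, p$sdlog)
    diam[i] <- round(pmin(pmax(d, p$range[1]), p$range[2]), 1)
  }
  tab$diameter_mm <- diam

  # per-case composition: grade defaults jittered on the log scale
  set.seed(child_seed(recipe$seed, "composition"))
  frac <- matrix(0, n_all, 3, dimnames = list(NULL, c("dense", "air_like", "intermediate")))
  for (i in seq_len(n_all)) {
    base <- vapply(default_components(g[i]), function(c) c$target_fraction, 0)
    f <- base * exp(rnorm(3, 0, recipe$fraction_jitter_sd))
    frac[i, ] <- f / sum(f)
  }

  cases <- if (keep_volumes && images) vector("list", n_all) else NULL
  tab$seed <- vapply(seq_len(n_all), function(i) child_seed(recipe$seed, paste0("image", i)), 0L)
  for (i in seq_len(if (images) n_all else 0L)) {
    comps <- default_components(g[i])
    for (nm in names(comps)) comps[[nm]]$target_fraction <- frac[i, nm]
    nr <- nodule_recipe(grade = g[i], diameter_mm = tab$diameter_mm[i],
                        spacing_mm = recipe$spacing_mm, components = comps,
                        interface_scale = recipe$interface_scale,
                        seed = tab$seed[i])
    nod <- generate_nodule(nr)
    nod$case_id <- tab$case_id[i]
    if (!is.null(out_dir)) {
      write_nifti_volume(nod$volume, file.path(out_dir, paste0(tab$case_id[i], "_image.nii.gz")))
      write_nifti_volume(nod$mask, file.path(out_dir, paste0(tab$case_id[i], "_mask.nii.gz")))
    }
    if (keep_volumes && images) cases[[i]] <- nod
  }
  if (!is.null(out_dir))
    write.table(tab, file.path(out_dir, "cohort.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  list(table = tab, cases = cases)
}
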