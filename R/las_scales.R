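#' Built-in linear appraisal scale catalogue
#'
#' The CAPRIGRAN Murciano-Granadina scale system: 17 doe traits and 10 buck
#' traits grouped into major areas (structure & capacity, dairy structure,
#' mammary system, legs & aplomb). Each measurable trait carries the
#' zoometric range, the measurement anchored to the scale midpoint (score 5)
#' and the published optimum (often split by parity/age: primipara vs
#' multipara does, bucklings vs adult bucks). Purely categorical traits
#' (body depth, angularity, bone quality, the rear-leg views, mobility) are
#' scored directly by the rater and carry no measurement map. `proposal`
#' selects the revised narrower point ranges; `classic` is the historical
#' 1-9 system used by the genetic evaluations.
#'
#' @param sex_status `"doe"` or `"buck"`.
#' @param scale_set `"classic"` (1-9 everywhere) or `"proposal"`.
#' @return named list of `TraitScaleDefinition` lists with fields `trait`,
#'   `major_area`, `applies_to`, `type` (`"measured"`/`"categorical"`),
#'   `zoometric_min`, `zoometric_max`, `midpoint`, `units`,
#'   `optimum_zoometric` (vector, parity-ordered), `optimum_score` (matching
#'   vector), `optimum_score_agg` (single mature-animal optimum used by
#'   [area_percents()]), `las_min`, `las_max`, `direction`, `knots`
#'   (matrix measurement x score, or NULL) and `shared_with_bucks`.
#' @export
builtin_scales <- function(sex_status = c("doe", "buck"),
                           scale_set = c("classic", "proposal")) {
  sex_status <- match.arg(sex_status)
  scale_set <- match.arg(scale_set)

  rescale_score <- function(s, las_max) {
    if (las_max == 9L) s else round_half_away(1 + (s - 1) * (las_max - 1) / 8)
  }

  def <- function(trait, area, type, zmin = NA, zmax = NA, mid = NA,
                  units = NA_character_, opt_z = NA, opt_score,
                  proposal_max = 9L, shared = FALSE, knots = NULL) {
    las_max <- if (scale_set == "classic") 9L else as.integer(proposal_max)
    opt_agg <- rescale_score(max(opt_score), las_max)
    list(trait = trait, major_area = area, type = type,
         zoometric_min = zmin, zoometric_max = zmax, midpoint = mid,
         units = units, optimum_zoometric = opt_z,
         optimum_score = as.integer(rescale_score(opt_score, las_max)),
         optimum_score_agg = as.integer(opt_agg),
         las_min = 1L, las_max = las_max,
         direction = if (!is.na(zmin) && !is.na(zmax) && zmax < zmin)
                       "decreasing" else "increasing",
         knots = knots, shared_with_bucks = shared)
  }

  doe <- list(
    def("stature", "structure_capacity", "measured", 62, 78, 70, "cm",
        opt_z = c(72, 74), opt_score = c(6, 7)),
    def("chest_width", "structure_capacity", "measured", 15, 23, 19, "cm",
        opt_z = c(20, 21), opt_score = c(6, 7)),
    def("body_depth", "structure_capacity", "categorical",
        opt_score = 7, proposal_max = 8, shared = TRUE),
    def("rump_width", "structure_capacity", "measured", 13, 21, 17, "cm",
        opt_z = c(18, 19), opt_score = c(6, 7), proposal_max = 7),
    def("rump_angle", "structure_capacity", "measured", 55, 31, 43, "deg",
        opt_z = 31, opt_score = 9, proposal_max = 7),
    def("angularity", "dairy_structure", "categorical",
        opt_score = 9, proposal_max = 10, shared = TRUE),
    def("bone_quality", "dairy_structure", "categorical",
        opt_score = 9, proposal_max = 5, shared = TRUE),
    def("anterior_insertion", "mammary_system", "measured", 45, 120, 90,
        "deg", opt_z = 120, opt_score = 9, proposal_max = 5,
        knots = cbind(measurement = c(45, 90, 120), score = c(1, 5, 9))),
    def("rear_insertion_height", "mammary_system", "measured", 11, 3, 7,
        "cm", opt_z = 3, opt_score = 9, proposal_max = 5),
    def("median_suspensor_ligament", "mammary_system", "measured", 1, 9, 5,
        "cm", opt_z = 5, opt_score = 5, proposal_max = 6),
    def("udder_width", "mammary_system", "measured", 3, 11, 7, "cm",
        opt_z = 11, opt_score = 9, proposal_max = 5),
    def("udder_depth", "mammary_system", "measured", -10, 10, 0, "cm",
        opt_z = c(-5, 0), opt_score = c(3, 5)),
    def("nipple_placement", "mammary_system", "measured", 90, 0, 45, "deg",
        opt_z = 0, opt_score = 9, proposal_max = 6),
    # range printed in degrees in the source table; units are cm
    # (optimum 2 cm, midpoint 2.5 cm)
    def("nipple_diameter", "mammary_system", "measured", 0.5, 4.5, 2.5,
        "cm", opt_z = 2, opt_score = 4),
    def("rear_legs_rear_view", "legs_aplomb", "categorical",
        opt_score = 9, proposal_max = 7, shared = TRUE),
    def("rear_legs_side_view", "legs_aplomb", "categorical",
        opt_score = 5, proposal_max = 7, shared = TRUE),
    def("mobility", "legs_aplomb", "categorical",
        opt_score = 9, proposal_max = 5, shared = TRUE)
  )

  if (sex_status == "doe") {
    for (i in seq_along(doe)) doe[[i]]$applies_to <-
      if (doe[[i]]$shared_with_bucks) "both" else "does"
    names(doe) <- vapply(doe, `[[`, "", "trait")
    return(doe)
  }

  buck <- list(
    def("stature", "structure_capacity", "measured", 68, 92, 80, "cm",
        opt_z = c(83, 86), opt_score = c(6, 7), proposal_max = 10),
    def("chest_width", "structure_capacity", "measured", 15, 31, 23, "cm",
        opt_z = c(25, 27), opt_score = c(6, 7), proposal_max = 11),
    doe[[which(vapply(doe, `[[`, "", "trait") == "body_depth")]],
    def("rump_width", "structure_capacity", "measured", 14, 22, 18, "cm",
        opt_z = c(19, 20), opt_score = c(6, 7), proposal_max = 5),
    def("rump_angle", "structure_capacity", "measured", 55, 31, 43, "deg",
        opt_z = 31, opt_score = 9, proposal_max = 6),
    doe[[which(vapply(doe, `[[`, "", "trait") == "angularity")]],
    doe[[which(vapply(doe, `[[`, "", "trait") == "bone_quality")]],
    doe[[which(vapply(doe, `[[`, "", "trait") == "rear_legs_rear_view")]],
    doe[[which(vapply(doe, `[[`, "", "trait") == "rear_legs_side_view")]],
    doe[[which(vapply(doe, `[[`, "", "trait") == "mobility")]]
  )
  for (i in seq_along(buck)) buck[[i]]$applies_to <-
    if (buck[[i]]$shared_with_bucks) "both" else "bucks"
  names(buck) <- vapply(buck, `[[`, "", "trait")
  buck
}

#' Major-area weights of the final appraisal score
#'
#' Does: 25% structure & capacity, 15% dairy structure, 40% mammary system,
#' 20% legs & aplomb. Bucks (no mammary system): 50 / 20 / 30.
#'
#' @param sex_status `"doe"` or `"buck"`.
#' @return named numeric vector summing to 100.
#' @export
area_weights <- function(sex_status = c("doe", "buck")) {
  sex_status <- match.arg(sex_status)
  w <- if (sex_status == "doe") {
    c(structure_capacity = 25, dairy_structure = 15,
      mammary_system = 40, legs_aplomb = 20)
  } else {
    c(structure_capacity = 50, dairy_structure = 20, legs_aplomb = 30)
  }
  stopifnot(sum(w) == 100)
  w
}

#' Translate a zoometric measurement into a linear appraisal score
#'
#' Piecewise-linear interpolation anchored at (min -> 1, midpoint -> 5,
#' max -> 9), or through explicit knots for non-uniform scales (anterior
#' insertion: 45deg -> 1, 90deg -> 5, 120deg -> 9). Decreasing scales (e.g.
#' rump angle 55deg-31deg) map the lower measurement to the higher score.
#' On a narrower `proposal` scale the 1-9 anchors are rescaled linearly onto
#' the reduced range. Result is rounded half-away-from-zero and clipped to
#' the point range.
#'
#' @param value numeric measurement(s) in the trait's units.
#' @param scale a `TraitScaleDefinition` from [builtin_scales()].
#' @return integer score(s).
#' @export
zoometric_to_las <- function(value, scale) {
  if (scale$type == "categorical") {
    stop("trait '", scale$trait,
         "' is rater-scored (categorical); supply a score, not a measurement")
  }
  if (!is.numeric(value) || any(!is.finite(value))) {
    stop("measurement must be finite numeric")
  }
  kn <- scale$knots
  if (is.null(kn)) {
    kn <- cbind(measurement = c(scale$zoometric_min, scale$midpoint,
                                scale$zoometric_max),
                score = c(1, 5, 9))
  }
  o <- order(kn[, 1])
  raw <- stats::approx(kn[o, 1], kn[o, 2], xout = value, rule = 2)$y
  if (scale$las_max != 9L) {
    raw <- 1 + (raw - 1) * (scale$las_max - 1) / 8
  }
  sc <- round_half_away(raw)
  as.integer(pmin(pmax(sc, scale$las_min), scale$las_max))
}

#' Invert a linear appraisal score
#'
#' The scale-inversion proposal for traits whose optimum sits at the low
#' measurement end (rear insertion height, anterior insertion): on a
#' `1..K` scale the score `s` becomes `K + 1 - s`, an involution.
#'
#' @param score integer score(s) within the scale's point range.
#' @param scale a `TraitScaleDefinition`.
#' @return integer score(s).
#' @export
invert_scale <- function(score, scale) {
  if (any(score < scale$las_min | score > scale$las_max)) {
    stop("score outside [", scale$las_min, ", ", scale$las_max, "]")
  }
  as.integer(scale$las_max + 1L - score)
}

#' Major-area subscores as percent of optimum
#'
#' Package convention (the published system does not print its aggregation
#' rule): each trait contributes `min(score / optimum, 1)` against the
#' mature-animal optimum score, and the area subscore is the mean
#' contribution times 100, so scoring every trait at its optimum gives 100%.
#'
#' @param scores named numeric/integer vector of trait scores.
#' @param sex_status `"doe"` or `"buck"`.
#' @param scale_set passed to [builtin_scales()].
#' @return named numeric vector of per-area percents in \[0, 100\].
#' @export
area_percents <- function(scores, sex_status = c("doe", "buck"),
                          scale_set = "classic") {
  sex_status <- match.arg(sex_status)
  cat <- builtin_scales(sex_status, scale_set)
  missing_traits <- setdiff(names(cat), names(scores))
  if (length(missing_traits)) {
    stop("missing scores for: ", paste(missing_traits, collapse = ", "))
  }
  areas <- vapply(cat, `[[`, "", "major_area")
  opt <- vapply(cat, function(s) as.numeric(s$optimum_score_agg), 0)
  ratio <- pmin(as.numeric(scores[names(cat)]) / opt, 1)
  out <- tapply(ratio, areas, mean) * 100
  out[names(area_weights(sex_status))]
}

#' Final appraisal score and category qualification
#'
#' Weighted sum of the major-area percents with the sex-appropriate weights;
#' the rounded score is classified as IN (<= 69), R (70-74), B (75-79),
#' BB (80-84), MB (85-89) or E (>= 90).
#'
#' @param area_percents named vector of per-area percents in \[0, 100\].
#' @param sex_status `"doe"` or `"buck"`.
#' @return list with `score` (0-100) and `qualification`.
#' @export
final_score <- function(area_percents, sex_status = c("doe", "buck")) {
  sex_status <- match.arg(sex_status)
  w <- area_weights(sex_status)
  missing_areas <- setdiff(names(w), names(area_percents))
  if (length(missing_areas)) {
    stop("missing area percent(s) for ", sex_status, ": ",
         paste(missing_areas, collapse = ", "))
  }
  ap <- area_percents[names(w)]
  if (any(ap < 0 | ap > 100)) stop("area percents must lie in [0, 100]")
  score <- sum(w * ap) / 100
  r <- round_half_away(score)
  qual <- if (r <= 69) "IN" else if (r <= 74) "R" else if (r <= 79) "B" else
          if (r <= 84) "BB" else if (r <= 89) "MB" else "E"
  list(score = score, qualification = qual)
}

#' Score a table of appraisal records
#'
#' Produces one ScoreCard row per animal: trait scores (translating measured
#' traits from zoometry when `from_measurements = TRUE`), optional scale
#' inversion for rear insertion height and anterior insertion, area
#' subscores, final score and qualification.
#'
#' @param records data frame with an `animal` column and one column per
#'   trait of the catalogue.
#' @param sex_status `"doe"` or `"buck"`.
#' @param from_measurements translate measured traits from zoometry first.
#' @param invert_policy apply [invert_scale()] to rear insertion height and
#'   anterior insertion.
#' @param scale_set passed to [builtin_scales()].
#' @return data frame: animal, trait scores, area percents, `final_score`,
#'   `qualification`.
#' @export
score_records <- function(records, sex_status = c("doe", "buck"),
                          from_measurements = FALSE, invert_policy = FALSE,
                          scale_set = "classic") {
  sex_status <- match.arg(sex_status)
  cat <- builtin_scales(sex_status, scale_set)
  invert_traits <- c("rear_insertion_height", "anterior_insertion")
  rows <- lapply(seq_len(nrow(records)), function(r) {
    sc <- vapply(names(cat), function(tr) {
      v <- records[[tr]][r]
      s <- if (from_measurements && cat[[tr]]$type == "measured") {
        zoometric_to_las(v, cat[[tr]])
      } else as.integer(v)
      if (invert_policy && tr %in% invert_traits) {
        s <- invert_scale(s, cat[[tr]])
      }
      s
    }, integer(1))
    ap <- area_percents(sc, sex_status, scale_set)
    fs <- final_score(ap, sex_status)
    data.frame(as.list(sc), as.list(ap), final_score = fs$score,
               qualification = fs$qualification)
  })
  cbind(animal = records$animal, do.call(rbind, rows))
}

#' Export / import the scale catalogue as a config file
#'
#' The catalogue round-trips through YAML so a breeding programme can
#' override ranges or optima without touching code.
#'
#' @param scales list of `TraitScaleDefinition`s.
#' @param path output file.
#' @export
write_scales <- function(scales, path) {
  ser <- lapply(scales, function(s) {
    if (!is.null(s$knots)) s$knots <- as.data.frame(s$knots)
    s
  })
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname write_scales
#' @export
read_scales <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(s) {
    if (!is.null(s$knots)) {
      s$knots <- cbind(measurement = as.numeric(s$knots$measurement),
                       score = as.numeric(s$knots$score))
    }
    for (fld in c("zoometric_min", "zoometric_max", "midpoint")) {
      s[[fld]] <- if (is.null(s[[fld]])) NA else as.numeric(s[[fld]])
    }
    s
  })
}
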