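#' Pooled non-vertebrate mass-loss fraction
#'
#' Estimates the fraction of carcass mass lost to causes other than
#' vertebrate scavenging (invertebrates, microbial decomposition,
#' desiccation) by pooling caged control carcasses with experimental
#' carcasses at which no scavenging behaviour was recorded:
#' `sum(initial - final) / sum(initial)`.
#'
#' @param controls Deployment rows for the control carcasses.
#' @param unscavenged Optional deployment rows for unscavenged experimental
#'   carcasses, pooled with the controls.
#' @return A single fraction in `[0, 1]`.
#' @examples
#' ctl <- data.frame(initial_mass_g = c(250, 300), final_mass_g = c(240, 280),
#'                   removed = FALSE)
#' nonvertebrate_loss_fraction(ctl)  # 30/550
#' @export
nonvertebrate_loss_fraction <- function(controls, unscavenged = NULL) {
  d <- rbind(controls[, c("initial_mass_g", "final_mass_g", "removed")],
             if (!is.null(unscavenged) && nrow(unscavenged)) {
               unscavenged[, c("initial_mass_g", "final_mass_g", "removed")]
             })
  if (is.null(d) || nrow(d) == 0L) {
    abort_data("no control or unscavenged carcasses to estimate the non-vertebrate loss fraction")
  }
  if (any(d$removed)) {
    abort_validation("removed carcasses cannot inform the non-vertebrate loss fraction")
  }
  frac <- sum(d$initial_mass_g - d$final_mass_g) / sum(d$initial_mass_g)
  min(1, max(0, frac))
}

#' Vertebrate-attributable mass loss of a carcass
#'
#' Measured loss is `initial - final`, except that a carcass removed whole
#' from camera view is taken as fully consumed elsewhere, so its loss is its
#' entire initial mass. The non-vertebrate share `fraction * initial` is
#' subtracted and the result floored at zero.
#'
#' @param deployments Deployment rows (`initial_mass_g`, `final_mass_g`,
#'   `removed`).
#' @param fraction Non-vertebrate loss fraction in `[0, 1]`.
#' @return Numeric vector of adjusted vertebrate-attributable losses, grams.
#' @examples
#' d <- data.frame(initial_mass_g = 280, final_mass_g = 0, removed = TRUE)
#' adjust_loss(d, 0.096)  # 280 * 0.904
#' @export
adjust_loss <- function(deployments, fraction) {
  check_fraction(fraction, "fraction")
  loss <- measured_loss(deployments)
  pmax(0, loss - fraction * deployments$initial_mass_g)
}

measured_loss <- function(deployments) {
  ifelse(deployments$removed, deployments$initial_mass_g,
         deployments$initial_mass_g - deployments$final_mass_g)
}

#' Calibrate the in-situ consumption rate
#'
#' Least squares through the origin of adjusted vertebrate loss on summed
#' body-mass-weighted eating time over carcasses that were scavenged but not
#' removed: `kappa = sum(L * S) / sum(S^2)`, in grams per kilogram of
#' scavenger per minute of eating. `kappa` converts observed eating effort
#' into grams, which is what allows pre-removal in-situ consumption to be
#' split from the whole-carcass remover's credit.
#'
#' @param adjusted_loss_g Adjusted losses `L` (grams), one per carcass.
#' @param mass_time_kg_min Matching effort sums `S = sum_i m_i t_i`
#'   (kg times minutes).
#' @return `kappa` (>= 0).
#' @examples
#' calibrate_kappa(90, 11.4)              # one-point ratio, 7.895
#' calibrate_kappa(c(90, 50), c(11.4, 5)) # 1276 / 154.96
#' @export
calibrate_kappa <- function(adjusted_loss_g, mass_time_kg_min) {
  if (length(adjusted_loss_g) != length(mass_time_kg_min)) {
    abort_validation("adjusted_loss_g and mass_time_kg_min must have equal length")
  }
  use <- which(mass_time_kg_min > 0)
  if (!length(use)) {
    abort_calibration("no carcass with positive mass-time effort; cannot calibrate kappa")
  }
  L <- adjusted_loss_g[use]
  S <- mass_time_kg_min[use]
  if (any(L < 0)) abort_validation("adjusted losses must be nonnegative")
  sum(L * S) / sum(S^2)
}

#' Partition one carcass's adjusted loss among species
#'
#' Non-removed carcass: species `i` receives
#' `adjusted * m_i t_i / sum_j m_j t_j` — biomass removed proportional both
#' to time spent feeding and to scavenger body mass. With no eating effort,
#' the loss stays unattributed. Removed carcass: under the `"kappa"` rule
#' each in-situ eater receives `kappa * m_i * t_i` (rescaled proportionally
#' if the sum exceeds the adjusted loss) and the remover receives the
#' remainder; under the `"proportional"` fallback the remover is treated as
#' the sole consumer of the whole adjusted loss.
#'
#' @param adjusted_loss_g Adjusted vertebrate-attributable loss, grams.
#' @param eating_min_by_species Named vector of eating minutes per species.
#' @param remover Species code of the whole-carcass remover, or `NULL` for a
#'   non-removed carcass.
#' @param body_masses Named vector of body masses in grams
#'   (see [default_body_masses()]).
#' @param kappa Calibrated in-situ rate from [calibrate_kappa()]; may be
#'   `NULL` when `method = "proportional"` or nothing was eaten in situ.
#' @param method `"kappa"` or `"proportional"` removal split rule.
#' @return List with `grams` (named per species) and `unattributed_g`; the
#'   two always sum to `adjusted_loss_g`.
#' @export
allocate_carcass <- function(adjusted_loss_g, eating_min_by_species,
                             remover = NULL, body_masses = default_body_masses(),
                             kappa = NULL,
                             method = c("kappa", "proportional")) {
  method <- match.arg(method)
  check_number(adjusted_loss_g, "adjusted_loss_g", lower = 0)
  eat <- eating_min_by_species[eating_min_by_species > 0]
  unknown <- setdiff(c(names(eat), remover), names(body_masses))
  if (length(unknown)) {
    abort_validation(paste("species missing from body-mass table:",
                           paste(unknown, collapse = ", ")))
  }
  species <- union(names(eat), remover)
  grams <- stats::setNames(numeric(length(species)), species)
  w <- body_masses[names(eat)] / 1000 * eat   # kg * min
  if (is.null(remover)) {
    if (length(w) && sum(w) > 0) {
      grams[names(eat)] <- adjusted_loss_g * w / sum(w)
      unatt <- adjusted_loss_g - sum(grams)
    } else {
      unatt <- adjusted_loss_g
    }
  } else {
    if (method == "kappa" && !is.null(kappa) && length(w)) {
      x <- kappa * w
      if (sum(x) > adjusted_loss_g && sum(x) > 0) {
        x <- x * adjusted_loss_g / sum(x)
      }
      grams[names(eat)] <- x
      grams[remover] <- grams[remover] + (adjusted_loss_g - sum(x))
    } else {
      grams[remover] <- adjusted_loss_g
    }
    unatt <- adjusted_loss_g - sum(grams)
  }
  list(grams = grams, unattributed_g = unatt)
}

#' Round half away from zero
#'
#' Display percentages use conventional half-up rounding; base [round()] is
#' round-half-even, which does not reproduce printed ledgers.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return `x` rounded half-up.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage ledger of biomass by species
#'
#' Turns per-species gram totals and a denominator (total deployed biomass in
#' the chosen scope) into the standard ledger: raw percentages, per-species
#' display percentages rounded half-up to the nearest integer, and a `TOTAL`
#' row whose display percentage is the sum of the rounded per-species
#' percentages (the convention of the printed ledgers this package
#' reproduces).
#'
#' @param species_g Named numeric vector: grams attributed per species.
#' @param deployed_g Total deployed biomass in scope, grams.
#' @return Data frame `species`, `grams`, `pct`, `pct_display`; the last row
#'   is `TOTAL`. Percentages are `NA` when `deployed_g` is not positive
#'   (empty scope).
#' @examples
#' biomass_ledger(c(CROW = 3586, MAGPIE = 1416, FOX = 3018), 18610)
#' @export
biomass_ledger <- function(species_g, deployed_g) {
  if (is.null(names(species_g)) || any(!nzchar(names(species_g)))) {
    abort_validation("species_g must be a named vector")
  }
  pct <- if (isTRUE(deployed_g > 0)) 100 * species_g / deployed_g else
    rep(NA_real_, length(species_g))
  disp <- round_half_up(pct)
  data.frame(
    species = c(names(species_g), "TOTAL"),
    grams = c(unname(species_g), sum(species_g)),
    pct = c(unname(pct), if (isTRUE(deployed_g > 0)) 100 * sum(species_g) / deployed_g else NA_real_),
    pct_display = c(unname(disp), sum(disp)),
    row.names = NULL
  )
}

#' Partition a study's carcass biomass loss among scavenger species
#'
#' The full attribution analysis. Estimates the pooled non-vertebrate loss
#' fraction from controls and unscavenged carcasses (unless supplied),
#' adjusts each carcass's measured loss (removed carcasses count as fully
#' consumed), calibrates the in-situ consumption rate `kappa` on scavenged
#' non-removed carcasses, allocates each carcass's adjusted loss among
#' species by feeding-time-by-body-mass weights (with the `kappa` split
#' between pre-removal eating and remover credit on removed carcasses), and
#' aggregates grams and percentages under three scopes:
#' \describe{
#'   \item{ALL}{denominator is the total deployed experimental biomass;}
#'   \item{SCAVENGED_ONLY}{carcasses with any `EATING`/`REMOVING`
#'     observation;}
#'   \item{FOX_ACCESSIBLE_ONLY}{scavenged carcasses at sites with
#'     `access_class == "ALL"`.}
#' }
#'
#' @param deployments Deployment table (experimental and control rows).
#' @param observations Observation table from [extract_observations()].
#' @param body_masses Named body-mass vector, grams.
#' @param fraction Optional known non-vertebrate loss fraction; estimated
#'   from the data when `NULL`.
#' @param method Removal split rule: `"kappa"` (default) or
#'   `"proportional"` (remover takes the whole adjusted loss).
#' @param fraction_scope Apply the non-vertebrate adjustment per carcass
#'   (default) or rescale so the study-wide non-vertebrate pool is exactly
#'   `fraction * total deployed` (`"study_wide"`).
#' @return An object of class `carcass_attribution`; see Details. Access the
#'   per-carcass table via `$carcass`, long-format allocations via
#'   `$allocations`, and the scope ledgers via `$summary`.
#' @seealso [biomass_ledger()], [calibrate_kappa()], [allocate_carcass()]
#' @export
attribute_study <- function(deployments, observations,
                            body_masses = default_body_masses(),
                            fraction = NULL,
                            method = c("kappa", "proportional"),
                            fraction_scope = c("per_carcass", "study_wide")) {
  method <- match.arg(method)
  fraction_scope <- match.arg(fraction_scope)
  validate_deployments(deployments)
  if (nrow(observations) &&
      !all(observations$carcass_id %in% deployments$carcass_id)) {
    abort_integrity("observations reference carcasses absent from deployments")
  }

  ctrl <- deployments[deployments$is_control, , drop = FALSE]
  exp <- deployments[!deployments$is_control, , drop = FALSE]
  if (nrow(exp) == 0L) abort_data("no experimental carcasses in study")
  obs <- observations[observations$carcass_id %in% exp$carcass_id, ,
                      drop = FALSE]

  scav_obs <- obs[obs$behavior %in% SCAVENGING_BEHAVIORS, , drop = FALSE]
  scavenged <- exp$carcass_id %in% scav_obs$carcass_id
  unscav <- exp[!scavenged & !exp$removed, , drop = FALSE]

  if (is.null(fraction)) {
    fraction <- nonvertebrate_loss_fraction(ctrl, unscav)
  } else {
    check_fraction(fraction, "fraction")
  }

  loss <- measured_loss(exp)
  adjusted <- adjust_loss(exp, fraction)
  if (fraction_scope == "study_wide") {
    pool <- max(0, sum(loss) - fraction * sum(exp$initial_mass_g))
    if (sum(adjusted) > 0) adjusted <- adjusted * pool / sum(adjusted)
  }
  nonvert <- loss - adjusted

  # eating effort S = sum_i m_i t_i per carcass, and eating minutes matrix
  eat_tab <- eating_time_by_species(obs, species = names(body_masses),
                                    carcasses = exp$carcass_id)
  unknown <- setdiff(unique(eat_tab$species[eat_tab$eating_min > 0]),
                     names(body_masses))
  if (length(unknown)) {
    abort_validation(paste("species missing from body-mass table:",
                           paste(unknown, collapse = ", ")))
  }

  # remover = species of the last REMOVING observation of a removed carcass
  removers <- stats::setNames(rep(NA_character_, nrow(exp)), exp$carcass_id)
  rem_obs <- scav_obs[scav_obs$behavior == "REMOVING", , drop = FALSE]
  if (nrow(rem_obs)) {
    rem_obs <- rem_obs[order(rem_obs$start), , drop = FALSE]
    last <- tapply(seq_len(nrow(rem_obs)), rem_obs$carcass_id, max)
    found <- intersect(names(last), exp$carcass_id[exp$removed])
    removers[found] <- rem_obs$species[last[found]]
  }

  effort <- vapply(exp$carcass_id, function(id) {
    rows <- eat_tab[eat_tab$carcass_id == id, , drop = FALSE]
    sum(body_masses[rows$species] / 1000 * rows$eating_min)
  }, numeric(1))

  calib <- !exp$removed & scavenged & effort > 0
  kappa <- if (any(calib)) {
    calibrate_kappa(adjusted[calib], effort[calib])
  } else NA_real_

  species <- names(body_masses)
  alloc_rows <- vector("list", nrow(exp))
  unattributed <- numeric(nrow(exp))
  for (j in seq_len(nrow(exp))) {
    id <- exp$carcass_id[j]
    rows <- eat_tab[eat_tab$carcass_id == id & eat_tab$eating_min > 0, ,
                    drop = FALSE]
    mins <- stats::setNames(rows$eating_min, rows$species)
    remover <- if (exp$removed[j] && !is.na(removers[id])) removers[[id]] else NULL
    a <- allocate_carcass(adjusted[j], mins, remover, body_masses,
                          kappa = if (is.na(kappa)) NULL else kappa,
                          method = method)
    unattributed[j] <- a$unattributed_g
    if (length(a$grams)) {
      alloc_rows[[j]] <- data.frame(carcass_id = id,
                                    species = names(a$grams),
                                    grams = unname(a$grams))
    }
  }
  allocations <- do.call(rbind, Filter(Negate(is.null), alloc_rows))
  if (is.null(allocations)) {
    allocations <- data.frame(carcass_id = character(0),
                              species = character(0), grams = numeric(0))
  }

  carcass <- data.frame(
    carcass_id = exp$carcass_id,
    site_id = exp$site_id,
    access_class = exp$access_class,
    initial_mass_g = exp$initial_mass_g,
    final_mass_g = exp$final_mass_g,
    loss_g = loss,
    nonvertebrate_g = nonvert,
    adjusted_g = adjusted,
    allocated_g = adjusted - unattributed,
    unattributed_g = unattributed,
    scavenged = scavenged,
    removed = exp$removed,
    remover = unname(removers),
    row.names = NULL
  )

  scope_sets <- list(
    ALL = exp$carcass_id,
    SCAVENGED_ONLY = exp$carcass_id[scavenged],
    FOX_ACCESSIBLE_ONLY = exp$carcass_id[scavenged & exp$access_class == "ALL"]
  )
  summary_rows <- lapply(names(scope_sets), function(sc) {
    set <- scope_sets[[sc]]
    denom <- sum(exp$initial_mass_g[exp$carcass_id %in% set])
    g <- vapply(species, function(sp) {
      sum(allocations$grams[allocations$species == sp &
                              allocations$carcass_id %in% set])
    }, numeric(1))
    led <- biomass_ledger(g, denom)
    cbind(scope = sc, led, deployed_g = denom)
  })
  summary <- do.call(rbind, summary_rows)
  rownames(summary) <- NULL

  structure(list(
    carcass = carcass,
    allocations = allocations,
    summary = summary,
    fraction = fraction,
    kappa = kappa,
    method = method,
    fraction_scope = fraction_scope,
    body_masses = body_masses,
    n_experimental = nrow(exp),
    n_controls = nrow(ctrl),
    call = match.call()
  ), class = "carcass_attribution")
}

validate_deployments <- function(deployments) {
  required <- c("carcass_id", "initial_mass_g", "final_mass_g", "removed",
                "access_class", "is_control")
  missing <- setdiff(required, names(deployments))
  if (length(missing)) {
    abort_validation(paste("deployments lack column(s):",
                           paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(deployments$carcass_id)) {
    abort_integrity(sprintf("duplicate carcass id: %s",
                            deployments$carcass_id[duplicated(deployments$carcass_id)][1]))
  }
  bad <- deployments$final_mass_g > deployments$initial_mass_g |
    deployments$final_mass_g < 0
  if (any(bad)) {
    abort_integrity(sprintf("carcass %s has final mass outside [0, initial]",
                            deployments$carcass_id[bad][1]))
  }
  bad <- deployments$removed & deployments$final_mass_g != 0
  if (any(bad)) {
    abort_integrity(sprintf("removed carcass %s must have final mass 0",
                            deployments$carcass_id[bad][1]))
  }
  invisible(deployments)
}

#' @export
print.carcass_attribution <- function(x, digits = 3, ...) {
  cat(sprintf(
    "<carcass_attribution> %d experimental carcasses (%d scavenged, %d removed), %d controls\n",
    x$n_experimental, sum(x$carcass$scavenged), sum(x$carcass$removed),
    x$n_controls))
  cat(sprintf("  non-vertebrate loss fraction: %.4f (%.1f%%)\n",
              x$fraction, 100 * x$fraction))
  cat(sprintf("  kappa (in-situ rate): %s g/kg/min; removal rule: %s\n",
              if (is.na(x$kappa)) "not calibrated" else format(x$kappa, digits = digits),
              x$method))
  all_scope <- x$summary[x$summary$scope == "ALL", , drop = FALSE]
  cat("  biomass share of total deployed:\n")
  for (i in seq_len(nrow(all_scope))) {
    cat(sprintf("    %-12s %8.1f g  (%s%%)\n", all_scope$species[i],
                all_scope$grams[i],
                format(all_scope$pct_display[i])))
  }
  invisible(x)
}

#' @export
summary.carcass_attribution <- function(object, ...) {
  structure(list(attribution = object), class = "summary.carcass_attribution")
}

#' @export
print.summary.carcass_attribution <- function(x, ...) {
  a <- x$attribution
  print(a)
  cat("\nPer-scope ledgers (grams and % of scope biomass):\n")
  print(a$summary, row.names = FALSE)
  resid <- with(a$carcass,
                max(abs(allocated_g + unattributed_g + nonvertebrate_g - loss_g)))
  cat(sprintf("\nMax per-carcass conservation residual: %.2e g\n", resid))
  invisible(x)
}

#' @export
coef.carcass_attribution <- function(object, ...) {
  c(nonvertebrate_fraction = object$fraction, kappa = object$kappa)
}

#' @export
plot.carcass_attribution <- function(x, scope = "ALL", ...) {
  s <- x$summary[x$summary$scope == scope & x$summary$species != "TOTAL", ,
                 drop = FALSE]
  graphics::barplot(stats::setNames(s$pct, s$species),
                    ylab = "% of deployed biomass", main = scope, ...)
  invisible(x)
}
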