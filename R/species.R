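#' Behavioural profile of a scavenger species for the study simulator
#'
#' A species profile bundles the quantities the simulator needs to generate
#' realistic visits: how long the species takes to find a carcass, whether it
#' is active by day or night, how fast it eats relative to its body mass, and
#' how likely it is to carry a whole carcass away.
#'
#' Arrival latency is drawn from a gamma distribution parameterised by its
#' mean and standard deviation (minutes from deployment). `day_activity_prob`
#' is the probability that any given visit is placed between sunrise and
#' sunset. `eat_rate_g_per_kg_min` is the in-situ consumption rate in grams
#' per kilogram of scavenger body mass per minute of eating; a rate of zero
#' describes a species (such as the red fox in this system) that removes
#' carcasses whole but is never seen eating in place.
#'
#' @param code Short species code, e.g. `"CROW"`.
#' @param body_mass_g Mean adult body mass in grams (> 0).
#' @param mean_arrival_latency_min,sd_arrival_latency_min Mean and SD of the
#'   gamma-distributed latency from deployment to first arrival, minutes.
#' @param day_activity_prob Probability in `[0, 1]` that a visit occurs
#'   during the day.
#' @param eat_rate_g_per_kg_min In-situ consumption rate, g per kg body mass
#'   per minute of eating (>= 0).
#' @param bout_duration_mean_min Mean duration of an eating bout, minutes
#'   (exponentially distributed).
#' @param removal_prob_per_visit Probability in `[0, 1]` that a visit ends
#'   with the whole carcass being removed (only possible while mass remains).
#' @param guild `"avian"` or `"mammal"`; mammals cannot reach carcasses at
#'   avian-only (rooftop) sites.
#' @param attendance_prob Probability that the species discovers a given
#'   carcass at all during its deployment.
#' @param revisit_rate_per_h Poisson rate of return visits per hour after
#'   first arrival.
#' @param examine_duration_mean_min Mean duration of the examining prelude of
#'   a visit, minutes.
#' @param looking_prob Probability a visit opens with a short "looking"
#'   segment before the animal approaches.
#' @return An object of class `species_profile` (a named list).
#' @examples
#' species_profile("CROW", body_mass_g = 570,
#'                 mean_arrival_latency_min = 683, sd_arrival_latency_min = 460,
#'                 day_activity_prob = 0.98, eat_rate_g_per_kg_min = 2,
#'                 bout_duration_mean_min = 10, removal_prob_per_visit = 0.01)
#' @export
species_profile <- function(code, body_mass_g,
                            mean_arrival_latency_min, sd_arrival_latency_min,
                            day_activity_prob,
                            eat_rate_g_per_kg_min,
                            bout_duration_mean_min,
                            removal_prob_per_visit,
                            guild = c("avian", "mammal"),
                            attendance_prob = 1,
                            revisit_rate_per_h = 0.1,
                            examine_duration_mean_min = 1.5,
                            looking_prob = 0.5) {
  if (!is.character(code) || length(code) != 1L || !nzchar(code)) {
    abort_validation("field 'code' must be a non-empty string")
  }
  guild <- match.arg(guild)
  prof <- list(
    code = code,
    body_mass_g = check_number(body_mass_g, "body_mass_g", lower = 1e-9),
    mean_arrival_latency_min =
      check_number(mean_arrival_latency_min, "mean_arrival_latency_min", lower = 1e-9),
    sd_arrival_latency_min =
      check_number(sd_arrival_latency_min, "sd_arrival_latency_min", lower = 1e-9),
    day_activity_prob = check_fraction(day_activity_prob, "day_activity_prob"),
    eat_rate_g_per_kg_min =
      check_number(eat_rate_g_per_kg_min, "eat_rate_g_per_kg_min", lower = 0),
    bout_duration_mean_min =
      check_number(bout_duration_mean_min, "bout_duration_mean_min", lower = 0),
    removal_prob_per_visit =
      check_fraction(removal_prob_per_visit, "removal_prob_per_visit"),
    guild = guild,
    attendance_prob = check_fraction(attendance_prob, "attendance_prob"),
    revisit_rate_per_h =
      check_number(revisit_rate_per_h, "revisit_rate_per_h", lower = 0),
    examine_duration_mean_min =
      check_number(examine_duration_mean_min, "examine_duration_mean_min", lower = 0),
    looking_prob = check_fraction(looking_prob, "looking_prob")
  )
  structure(prof, class = "species_profile")
}

#' @export
print.species_profile <- function(x, ...) {
  cat(sprintf(
    "<species_profile> %s (%s, %g g)\n  arrival latency %g +/- %g min; P(day) = %g\n  eat %g g/kg/min, bouts ~%g min; P(remove|visit) = %g\n",
    x$code, x$guild, x$body_mass_g,
    x$mean_arrival_latency_min, x$sd_arrival_latency_min, x$day_activity_prob,
    x$eat_rate_g_per_kg_min, x$bout_duration_mean_min, x$removal_prob_per_visit))
  invisible(x)
}

#' Default scavenger body masses
#'
#' Stand-in mean adult body masses (grams) for the three urban scavengers:
#' carrion crow 570 g, Eurasian magpie 230 g, red fox 6500 g. These are
#' configurable defaults, not authoritative measurements; override them with
#' field- or literature-derived values where available.
#'
#' @return Named numeric vector of body masses in grams.
#' @export
default_body_masses <- function() {
  c(CROW = 570, MAGPIE = 230, FOX = 6500)
}

# Behaviour vocabulary --------------------------------------------------------

BEHAVIORS <- c("NONE", "LOOKING", "EXAMINING", "EATING", "REMOVING")
SCAVENGING_BEHAVIORS <- c("EATING", "REMOVING")
SPECIES_NONE <- "NONE"

#' Recognised behaviour codes
#'
#' The five behavioural interaction codes used in detection and observation
#' tables: `NONE`, `LOOKING`, `EXAMINING`, `EATING`, `REMOVING`. `EATING` and
#' `REMOVING` are the scavenging behaviours.
#'
#' @param scavenging If `TRUE`, return only the scavenging behaviours.
#' @return Character vector of behaviour codes.
#' @export
behavior_codes <- function(scavenging = FALSE) {
  if (scavenging) SCAVENGING_BEHAVIORS else BEHAVIORS
}
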