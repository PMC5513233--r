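#' Per-species attendance and activity summary
#'
#' Descriptive ledger per scavenger species: how many carcasses it attended
#' (any observation, including `NONE`/`LOOKING`), its share of all
#' observations and of scavenging-behaviour observations among the listed
#' species, total hours observed, total hours eating, and the number of
#' carcasses it removed whole. Attendance percentages are relative to all
#' experimental carcasses; shares are relative to the listed species only.
#'
#' @param deployments Deployment table.
#' @param observations Observation table.
#' @param species Species codes defining the community for share
#'   denominators; defaults to all species observed.
#' @return Data frame with one row per species: `species`,
#'   `n_carcasses_attended`, `attended_pct`, `n_observations`,
#'   `obs_share_pct`, `n_scavenging_obs`, `scavenging_share_pct`,
#'   `observed_hours`, `eating_hours`, `n_removed`. Shares are `NA` when
#'   there are no observations.
#' @export
attendance_summary <- function(deployments, observations, species = NULL) {
  exp <- deployments[!deployments$is_control, , drop = FALSE]
  obs <- observations[observations$carcass_id %in% exp$carcass_id &
                        observations$species %in%
                        (species %||% unique(observations$species)), ,
                      drop = FALSE]
  species <- species %||% sort(unique(obs$species))
  n_exp <- nrow(exp)
  total_obs <- nrow(obs)
  scav <- obs[obs$behavior %in% SCAVENGING_BEHAVIORS, , drop = FALSE]
  total_scav <- nrow(scav)
  rem <- removal_credits(exp, observations)
  out <- do.call(rbind, lapply(species, function(sp) {
    o <- obs[obs$species == sp, , drop = FALSE]
    so <- scav[scav$species == sp, , drop = FALSE]
    data.frame(
      species = sp,
      n_carcasses_attended = length(unique(o$carcass_id)),
      attended_pct = 100 * length(unique(o$carcass_id)) / n_exp,
      n_observations = nrow(o),
      obs_share_pct = if (total_obs) 100 * nrow(o) / total_obs else NA_real_,
      n_scavenging_obs = nrow(so),
      scavenging_share_pct = if (total_scav) 100 * nrow(so) / total_scav else NA_real_,
      observed_hours = sum(o$duration_min) / 60,
      eating_hours = sum(o$duration_min[o$behavior == "EATING"]) / 60,
      n_removed = sum(rem$species == sp)
    )
  }))
  rownames(out) <- NULL
  out
}

# One row per removed carcass credited to the species of its last REMOVING
# observation; removed carcasses with no REMOVING observation are dropped.
removal_credits <- function(deployments, observations) {
  rem_obs <- observations[observations$behavior == "REMOVING", , drop = FALSE]
  removed_ids <- deployments$carcass_id[deployments$removed]
  rem_obs <- rem_obs[rem_obs$carcass_id %in% removed_ids, , drop = FALSE]
  if (!nrow(rem_obs)) {
    return(data.frame(carcass_id = character(0), species = character(0)))
  }
  rem_obs <- rem_obs[order(rem_obs$start), , drop = FALSE]
  last <- tapply(seq_len(nrow(rem_obs)), rem_obs$carcass_id, max)
  data.frame(carcass_id = names(last),
             species = rem_obs$species[as.integer(last)],
             row.names = NULL)
}

#' Study-level detection and scavenging counts
#'
#' How many experimental carcasses were visited by any vertebrate, how many
#' were scavenged (any `EATING` or `REMOVING` observation), and what share
#' of all observations were scavenging behaviour.
#'
#' @param deployments Deployment table.
#' @param observations Observation table (all vertebrate species).
#' @return List: `n_experimental`, `n_attended`, `attended_pct`,
#'   `n_scavenged`, `scavenged_pct`, `n_observations`,
#'   `n_scavenging_observations`, `scavenging_obs_pct`.
#' @export
scavenging_detection_summary <- function(deployments, observations) {
  exp <- deployments[!deployments$is_control, , drop = FALSE]
  if (nrow(exp) == 0L) abort_data("empty study: no experimental carcasses")
  obs <- observations[observations$carcass_id %in% exp$carcass_id, ,
                      drop = FALSE]
  scav <- obs[obs$behavior %in% SCAVENGING_BEHAVIORS, , drop = FALSE]
  n_exp <- nrow(exp)
  n_att <- length(unique(obs$carcass_id))
  n_scav <- length(unique(scav$carcass_id))
  list(
    n_experimental = n_exp,
    n_attended = n_att,
    attended_pct = 100 * n_att / n_exp,
    n_scavenged = n_scav,
    scavenged_pct = 100 * n_scav / n_exp,
    n_observations = nrow(obs),
    n_scavenging_observations = nrow(scav),
    scavenging_obs_pct = if (nrow(obs)) 100 * nrow(scav) / nrow(obs) else NA_real_
  )
}

#' Mass loss by scavenger presence
#'
#' Group descriptives (no inference): mean and SD of carcass mass loss, in
#' grams and as a percentage of initial mass, for experimental carcasses
#' with and without scavenging activity. A removed carcass's loss is its
#' full initial mass.
#'
#' @param deployments Deployment table.
#' @param observations Observation table.
#' @return Data frame with rows `SCAVENGED` and `UNSCAVENGED`: `n`,
#'   `mean_loss_g`, `sd_loss_g`, `mean_loss_pct`, `sd_loss_pct`.
#' @export
mass_loss_comparison <- function(deployments, observations) {
  exp <- deployments[!deployments$is_control, , drop = FALSE]
  scav_ids <- unique(observations$carcass_id[
    observations$behavior %in% SCAVENGING_BEHAVIORS])
  grp <- ifelse(exp$carcass_id %in% scav_ids, "SCAVENGED", "UNSCAVENGED")
  loss <- measured_loss(exp)
  pct <- 100 * loss / exp$initial_mass_g
  out <- do.call(rbind, lapply(c("SCAVENGED", "UNSCAVENGED"), function(g) {
    k <- grp == g
    data.frame(group = g, n = sum(k),
               mean_loss_g = if (any(k)) mean(loss[k]) else NA_real_,
               sd_loss_g = if (sum(k) > 1) stats::sd(loss[k]) else NA_real_,
               mean_loss_pct = if (any(k)) mean(pct[k]) else NA_real_,
               sd_loss_pct = if (sum(k) > 1) stats::sd(pct[k]) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}
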