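# The scenario algebra: pure transformations of a site_config implementing
# the five process-improvement scenarios and their combinations.
#
#   P1  patients arriving via EMS stay on the EMS stretcher to imaging
#       (delete the transfer-to-ED-bay activity from the EMS graph)
#   P2  tPA bolus administered in the imaging area, regular and out of hours
#       (delete the imaging-to-ED travel activity everywhere and switch the
#       preparation to its shorter in-imaging variant)
#   P3  pre-registration of EMS patients (registration moves to the
#       pre-arrival phase: zero post-door time for EMS, unchanged for PV)
#   R1  treatment decision time reduced by 35% (scale by 0.65)
#   R2  tPA preparation time reduced by 35% (scale by 0.65; applied after
#       P2 it scales the in-imaging variant, i.e. the reductions compound)
#
# Process changes already in a site's baseline flags are no-ops ("current
# baseline"). P-codes are applied before R-codes, which makes composition
# order-independent.

.SCENARIO_CODES <- c("P1", "P2", "P3", "R1", "R2")

#' Specify a test scenario
#'
#' @param codes Character vector drawn from `P1, P2, P3, R1, R2`, or a
#'   single string like `"P1+P2"`; `"ALL"` expands to all five codes and
#'   `"BASELINE"` (or an empty vector) to none.
#' @param reduction_factor Multiplier used by the R-codes (default 0.65,
#'   i.e. a 35% reduction).
#' @return An object of class `scenario_spec`.
#' @examples
#' scenario_spec("P2")
#' scenario_spec("P1+P2+P3")
#' scenario_spec("ALL")
#' @export
scenario_spec <- function(codes = character(), reduction_factor = 0.65) {
  if (length(codes) == 1L && grepl("[+,]", codes)) {
    codes <- strsplit(codes, "[+,]")[[1]]
  }
  codes <- toupper(trimws(codes))
  codes <- codes[nzchar(codes)]
  if (length(codes) == 1L && codes == "ALL") codes <- .SCENARIO_CODES
  if (length(codes) == 1L && codes == "BASELINE") codes <- character(0)
  unknown <- setdiff(codes, .SCENARIO_CODES)
  if (length(unknown)) {
    stop("unknown scenario code(s): ", paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(codes)) stop("scenario codes must be unique")
  if (!(reduction_factor > 0 && reduction_factor <= 1)) {
    stop("reduction_factor must lie in (0, 1]")
  }
  structure(list(codes = codes, reduction_factor = reduction_factor),
            class = "scenario_spec")
}

as_scenario_spec <- function(x) {
  if (inherits(x, "scenario_spec")) x else scenario_spec(x)
}

scenario_label <- function(codes) {
  if (!length(codes)) "baseline" else paste(codes, collapse = "+")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario_spec %s (reduction factor %.2f)>\n",
              scenario_label(x$codes), x$reduction_factor))
  invisible(x)
}

#' Is a process change already part of the site baseline?
#'
#' @param config A [site_config()].
#' @param code One of `"P1"`, `"P2"`, `"P3"` (R-codes are never part of a
#'   baseline and always return `FALSE`).
#' @return `TRUE` if applying `code` would be a no-op at this site.
#' @export
is_baseline_noop <- function(config, code) {
  stopifnot(inherits(config, "site_config"))
  if (!is.character(code) || length(code) != 1L ||
      !(code %in% .SCENARIO_CODES)) {
    stop("code must be one of ", paste(.SCENARIO_CODES, collapse = ", "))
  }
  if (startsWith(code, "R")) return(FALSE)
  code %in% config$baseline_flags
}

# Remove one activity, rewiring its successors to its own predecessors so
# precedence through the deleted node is preserved.
.delete_activity <- function(config, id) {
  preds <- config$activities[[id]]$predecessors
  config$activities[[id]] <- NULL
  config$activities <- lapply(config$activities, function(a) {
    if (id %in% a$predecessors) {
      a$predecessors <- unique(c(setdiff(a$predecessors, id),
                                 intersect(preds, names(config$activities))))
    }
    a
  })
  config
}

# Locate the unique activity with a role, or fail naming the scenario.
.require_role <- function(config, role, code, pathway = NULL) {
  ids <- role_ids(config, role, pathway)
  if (length(ids) != 1L) {
    stop("scenario ", code, " requires exactly one role=", role,
         " activity", if (!is.null(pathway)) paste0(" on the ", pathway,
                                                    " pathway"),
         "; found ", length(ids))
  }
  ids
}

.scale_activity_dists <- function(config, id, factor) {
  a <- config$activities[[id]]
  same <- identical(a$duration_regular, a$duration_out_of_hours)
  a$duration_regular <- scale_dist(a$duration_regular, factor)
  a$duration_out_of_hours <- if (same) a$duration_regular else
    scale_dist(a$duration_out_of_hours, factor)
  config$activities[[id]] <- a
  config
}

#' Apply test scenarios to a site configuration
#'
#' Returns a new configuration with the scenario transformations applied;
#' the input is untouched. Process changes listed in the site's
#' `baseline_flags` are skipped ("current baseline"). P-codes are applied
#' before R-codes, so when P2 and R2 are combined the 35% reduction acts on
#' the in-imaging preparation variant. Re-applying a duration reduction to a
#' configuration that already carries it is refused, since scaling twice
#' would silently compound.
#'
#' @param config A valid [site_config()].
#' @param spec A [scenario_spec()] (or anything [scenario_spec()] accepts).
#' @return A transformed `site_config` tagged with its applied scenarios.
#' @examples
#' cfg <- default_site_configs()$site3_rural
#' cfg_p1 <- apply_scenarios(cfg, "P1")
#' length(cfg$activities) - length(cfg_p1$activities)  # transfer removed
#' @export
apply_scenarios <- function(config, spec) {
  assert_valid_config(config)
  spec <- as_scenario_spec(spec)
  repeated_r <- intersect(intersect(spec$codes, c("R1", "R2")),
                          config$applied_scenarios)
  if (length(repeated_r)) {
    stop("duration reduction(s) already applied to this config: ",
         paste(repeated_r, collapse = ", "))
  }
  f <- spec$reduction_factor
  codes <- intersect(.SCENARIO_CODES, spec$codes)  # P-codes first, fixed order

  for (code in codes) {
    if (is_baseline_noop(config, code)) next
    # P-codes are idempotent: re-application to an already-transformed
    # config is a no-op, not an error
    if (startsWith(code, "P") && code %in% config$applied_scenarios) next
    config <- switch(code,
      P1 = {
        id <- .require_role(config, "transfer_to_ed_bay", "P1",
                            pathway = "EMS")
        .delete_activity(config, id)
      },
      P2 = {
        id <- .require_role(config, "travel_imaging_to_ed", "P2")
        config <- .delete_activity(config, id)
        prep <- .require_role(config, "tpa_prep", "P2")
        variant <- config$prep_in_imaging_variant
        if (is.null(variant)) {
          stop("scenario P2 requires a prep_in_imaging_variant distribution")
        }
        a <- config$activities[[prep]]
        a$duration_regular <- variant
        a$duration_out_of_hours <- variant
        config$activities[[prep]] <- a
        config
      },
      P3 = {
        id <- .require_role(config, "registration", "P3")
        config$activities[[id]]$phase <- "A"
        config
      },
      R1 = .scale_activity_dists(
        config, .require_role(config, "decision", "R1"), f),
      R2 = .scale_activity_dists(
        config, .require_role(config, "tpa_prep", "R2"), f)
    )
  }
  config$applied_scenarios <- union(config$applied_scenarios, spec$codes)
  assert_valid_config(config)
  config
}
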