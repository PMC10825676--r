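# Batch orchestration: process a manifest of heterogeneous test files,
# join all phenotypes on stalk x internode, and keep an exhaustive
# processing log (every file accounted for exactly once).

#' Default pipeline configuration
#'
#' Collects every tunable threshold and window of the analysis modules
#' in one nested list that round-trips losslessly through YAML
#' ([write_pipeline_config()] / [read_pipeline_config()]).
#'
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function() {
  structure(list(
    darling = list(theta_on_deg = 2, theta_off_deg = 1,
                   failure_theta_deg = 15,
                   quantile_band = c(0.2, 0.8)),
    puncture = list(blank_threshold_N = 1, contact_min_N = 0.5,
                    noise_mult = 5, smooth_window = 21L, baseline_n = 200L),
    bending = list(max_deflection_mm = 6, quantile_band = c(0.2, 0.8)),
    internode = list(iou_threshold = 0.5),
    output_dir = ".",
    log_level = "info"
  ), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A \code{pipeline_config}.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  num <- unlist(cfg[c("darling", "puncture", "bending", "internode")])
  if (any(num <= 0)) stop("config thresholds must be positive", call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

process_one_file <- function(path, kind, config, puncture_counters) {
  switch(kind,
    darling = {
      res <- analyze_darling(read_darling_csv(path),
                             quantile_band = config$darling$quantile_band,
                             failure_theta = config$darling$failure_theta_deg)
      list(level = "stalk",
           row = data.frame(stalk_id = res$stalk_id,
                            bending_strength_Nm = res$bending_strength_Nm,
                            flexural_stiffness_Nm2 = res$flexural_stiffness_Nm2,
                            darling_r_squared = res$r_squared,
                            failure_note = res$failure_note,
                            timestamp = res$timestamp %||% NA_character_,
                            stringsAsFactors = FALSE))
    },
    puncture = {
      trace <- read_instron_csv(path)
      id <- trace$metadata$stalk_id %||% NA_character_
      idx <- trace$metadata$internode_index
      if (is.null(idx)) {
        key <- if (is.na(id)) "<none>" else id
        idx <- (puncture_counters[[key]] %||% 0L) + 1L
        puncture_counters[[key]] <- idx
      }
      res <- puncture_phenotypes(
        trace, blank_threshold_N = config$puncture$blank_threshold_N,
        contact_min_N = config$puncture$contact_min_N,
        noise_mult = config$puncture$noise_mult,
        smooth_window = config$puncture$smooth_window,
        baseline_n = config$puncture$baseline_n)
      list(level = "internode", blank = res$is_blank,
           row = data.frame(stalk_id = id, internode_index = idx,
                            minor_diameter_mm = res$minor_diameter_mm,
                            rind_thickness_mm = res$rind_thickness_mm,
                            rind_penetration_resistance_N =
                              res$rind_penetration_resistance_N,
                            integrated_puncture_score_Nmm =
                              res$integrated_puncture_score_Nmm,
                            is_blank = res$is_blank,
                            stringsAsFactors = FALSE))
    },
    bending3pt = {
      trace <- read_instron_csv(path)
      m <- trace$metadata
      if (is.null(m$a_mm) || is.null(m$span_mm)) {
        stop(sprintf("%s: bending geometry (a_mm, span_mm) missing from metadata",
                     path), call. = FALSE)
      }
      geom <- span_geometry(a = m$a_mm, L = m$span_mm)
      res <- analyze_bending3pt(trace, geom,
                                max_deflection_mm = config$bending$max_deflection_mm)
      list(level = "stalk",
           row = data.frame(stalk_id = res$stalk_id %||% NA_character_,
                            bending3pt_strength_Nmm = res$bending_strength_Nmm,
                            bending3pt_stiffness_Nmm2 = res$flexural_stiffness_Nmm2,
                            bending3pt_discard_flag = res$discard_recommended,
                            stringsAsFactors = FALSE))
    },
    micro_bending = {
      trace <- read_instron_csv(path)
      res <- tissue_flexural_curve(trace,
                                   quantile_band = config$bending$quantile_band)
      list(level = "internode",
           row = data.frame(stalk_id = trace$metadata$stalk_id %||% NA_character_,
                            internode_index =
                              trace$metadata$internode_index %||% NA_real_,
                            youngs_modulus_MPa = res$youngs_modulus_MPa,
                            flexural_stress_at_failure_MPa =
                              res$flexural_stress_at_failure_MPa,
                            strain_at_failure = res$strain_at_failure,
                            stringsAsFactors = FALSE))
    },
    stop(sprintf("unknown test kind '%s' for %s", kind, path), call. = FALSE)
  )
}

merge_kind_tables <- function(tables, keys) {
  out <- NULL
  for (tab in tables) {
    out <- if (is.null(out)) tab else merge(out, tab, by = keys, all = TRUE)
  }
  out
}

#' Process a manifest of test files into one merged phenotype table
#'
#' Every file in the manifest is parsed and analysed according to its
#' kind (\code{darling}, \code{puncture}, \code{bending3pt},
#' \code{micro_bending}); internode-level phenotypes are outer-joined on
#' stalk x internode, stalk-level phenotypes are attached to every row
#' of their stalk. Missing measurements stay as explicit NA. The
#' processing log (one row per input file: processed / blank /
#' rejected, with the messages raised) is attached as
#' \code{attr(result, "log")}; within-plot chronology of field tests is
#' audited (warnings in \code{attr(result, "audit")}), never
#' auto-corrected.
#'
#' @param manifest data.frame with columns \code{path} and \code{kind}.
#' @param config A [pipeline_config()].
#' @return data.frame with one row per stalk x internode (internode NA
#'   for stalks with only whole-stalk measurements), ordered by stalk
#'   then internode.
#' @export
run_batch <- function(manifest, config = pipeline_config()) {
  stopifnot(is.data.frame(manifest), all(c("path", "kind") %in% names(manifest)))
  log_rows <- list()
  stalk_tables <- list()
  internode_tables <- list()
  counters <- new.env(parent = emptyenv())
  seen <- new.env(parent = emptyenv())

  for (i in seq_len(nrow(manifest))) {
    path <- manifest$path[[i]]
    kind <- manifest$kind[[i]]
    msgs <- character()
    res <- withCallingHandlers(
      tryCatch(process_one_file(path, kind, config, counters),
               error = function(e) e),
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    if (inherits(res, "error")) {
      log_rows[[i]] <- data.frame(path = path, kind = kind,
                                  status = "rejected",
                                  message = conditionMessage(res),
                                  stringsAsFactors = FALSE)
      next
    }
    dup_key <- paste(kind, res$row$stalk_id[[1L]],
                     if (res$level == "internode") res$row$internode_index[[1L]]
                     else "", sep = "\r")
    if (!is.null(seen[[dup_key]])) {
      stop(sprintf(
        "duplicate %s measurement for stalk %s%s: %s and %s", kind,
        res$row$stalk_id[[1L]],
        if (res$level == "internode") {
          sprintf(" internode %s", res$row$internode_index[[1L]])
        } else "",
        seen[[dup_key]], path), call. = FALSE)
    }
    seen[[dup_key]] <- path
    if (res$level == "stalk") {
      stalk_tables[[kind]] <- rbind(stalk_tables[[kind]], res$row)
    } else {
      internode_tables[[kind]] <- rbind(internode_tables[[kind]], res$row)
    }
    log_rows[[i]] <- data.frame(
      path = path, kind = kind,
      status = if (isTRUE(res$blank)) "blank" else "processed",
      message = paste(msgs, collapse = "; "), stringsAsFactors = FALSE)
  }
  log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(path = character(), kind = character(), status = character(),
               message = character(), stringsAsFactors = FALSE)

  internode <- merge_kind_tables(internode_tables,
                                 c("stalk_id", "internode_index"))
  stalk <- merge_kind_tables(stalk_tables, "stalk_id")
  out <- if (is.null(internode) && is.null(stalk)) {
    data.frame(stalk_id = character(), internode_index = numeric(),
               stringsAsFactors = FALSE)
  } else if (is.null(internode)) {
    cbind(stalk[, "stalk_id", drop = FALSE], internode_index = NA_real_,
          stalk[, setdiff(names(stalk), "stalk_id"), drop = FALSE])
  } else if (is.null(stalk)) {
    internode
  } else {
    merge(internode, stalk, by = "stalk_id", all = TRUE)
  }
  out <- out[order(out$stalk_id, out$internode_index), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "log") <- log
  attr(out, "audit") <- audit_chronology(stalk_tables[["darling"]])
  out
}

# Plants are labeled and tested sequentially within a plot, so the
# field-test timestamps should increase with stalk number. Violations
# are reported as audit messages, never auto-corrected.
audit_chronology <- function(darling_table) {
  if (is.null(darling_table) || !"timestamp" %in% names(darling_table)) {
    return(character())
  }
  ids <- lapply(darling_table$stalk_id, function(s) {
    tryCatch(parse_stalk_id(s), error = function(e) NULL)
  })
  ok <- !vapply(ids, is.null, logical(1L)) & !is.na(darling_table$timestamp)
  if (!any(ok)) return(character())
  tab <- data.frame(
    plot = vapply(ids[ok], function(x) {
      sprintf("%s%d_%d", x$location, x$year, x$plot)
    }, character(1L)),
    stalk = vapply(ids[ok], function(x) x$stalk, numeric(1L)),
    timestamp = darling_table$timestamp[ok], stringsAsFactors = FALSE)
  msgs <- character()
  for (p in unique(tab$plot)) {
    sub <- tab[tab$plot == p, ]
    sub <- sub[order(sub$stalk), ]
    if (is.unsorted(sub$timestamp)) {
      msgs <- c(msgs, sprintf(
        "plot %s: test timestamps not chronological in stalk order (check StalkIDs)",
        p))
    }
  }
  msgs
}
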