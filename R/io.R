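#' Write and read specimen geometry (JSON)
#'
#' One specimen per JSON document; a population file is a JSON array of
#' documents. Schema: `specimen_id`, `provenance`, `rng_seed_used`,
#' `outline {total_length_mm, total_width_mm, points [[x, y], ...]}`,
#' `amu {arc_point_indices}`, `modules [{index, side, boundary_curve,
#' medial_curve, ...}]`. Coordinates are serialized at full double
#' precision, so a write/read round trip is lossless to 1e-12. Unknown
#' keys are preserved with a warning.
#'
#' @param pop List of `specimen` objects (or a single specimen).
#' @param path File path.
#' @return `read_specimens` returns a list of `specimen` objects;
#'   `write_specimens` returns `path` invisibly.
#' @export
write_specimens <- function(pop, path) {
  if (inherits(pop, "specimen")) pop <- list(pop)
  docs <- lapply(pop, specimen_to_doc)
  jsonlite::write_json(docs, path, digits = NA, auto_unbox = TRUE,
                       null = "null", na = "null", pretty = FALSE)
  invisible(path)
}

specimen_to_doc <- function(s) {
  list(
    specimen_id = s$specimen_id,
    provenance = s$provenance,
    rng_seed_used = s$rng_seed_used,
    n_modules_true = s$n_modules_true,
    n_modules_observed = s$n_modules_observed,
    posterior_pole_index = s$posterior_pole_index,
    outline = list(total_length_mm = s$outline$total_length_mm,
                   total_width_mm = s$outline$total_width_mm,
                   n_vertices = s$outline$n_vertices,
                   points = s$outline$points),
    amu = list(arc_point_indices = s$amu$arc_point_indices),
    modules = lapply(s$modules, function(m) {
      list(index = m$index, side = m$side,
           midline_anchor = m$midline_anchor,
           margin_anchor = m$margin_anchor,
           margin_start_index = m$margin_start_index,
           margin_end_index = m$margin_end_index,
           boundary_curve = m$boundary_curve,
           medial_curve = m$medial_curve)
    }),
    generation = s$generation)
}

#' @rdname write_specimens
#' @export
read_specimens <- function(path) {
  docs <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (length(docs) == 0L) return(list())
  lapply(docs, doc_to_specimen)
}

doc_to_specimen <- function(doc) {
  known <- c("specimen_id", "provenance", "rng_seed_used", "n_modules_true",
             "n_modules_observed", "posterior_pole_index", "outline", "amu",
             "modules", "generation")
  required <- c("specimen_id", "outline", "amu", "modules")
  missing <- setdiff(required, names(doc))
  if (length(missing)) {
    stop(sprintf("specimen document missing field(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  extra <- setdiff(names(doc), known)
  if (length(extra)) {
    warning(sprintf("unknown specimen field(s) preserved: %s",
                    paste(extra, collapse = ", ")), call. = FALSE)
  }
  o <- doc$outline
  for (f in c("total_length_mm", "total_width_mm", "points")) {
    if (is.null(o[[f]])) {
      stop(sprintf("specimen document missing field(s): outline.%s", f),
           call. = FALSE)
    }
  }
  outline <- new_body_outline(as_point_matrix(o$points),
                              o$total_length_mm, o$total_width_mm,
                              o$n_vertices %||% nrow(as_point_matrix(o$points)))
  modules <- lapply(doc$modules, function(m) {
    new_module_geometry(m$index, m$side,
                        as.numeric(m$midline_anchor),
                        as.numeric(m$margin_anchor),
                        as_point_matrix(m$boundary_curve),
                        as_point_matrix(m$medial_curve),
                        m$margin_start_index %||% NA_integer_,
                        m$margin_end_index %||% NA_integer_)
  })
  n_true <- doc$n_modules_true %||%
    max(0L, vapply(modules, function(m) m$index, integer(1)))
  s <- new_specimen(
    doc$specimen_id, outline, modules,
    unlist(doc$amu$arc_point_indices),
    n_true,
    doc$posterior_pole_index %||% which.min(outline$points[, 1L]),
    provenance = doc$provenance %||% "digitized",
    rng_seed_used = doc$rng_seed_used %||% NA_integer_,
    generation = doc$generation %||% list())
  s$n_modules_observed <- as.integer(doc$n_modules_observed %||% n_true)
  s$extra_fields <- doc[extra]
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

measurement_columns <- c("specimen_id", "tl_mm", "tw_mm",
                         "n_modules_observed", "amu_margin_mm",
                         "module_index", "side", "mlm_mm", "mlom_mm",
                         "mw_mm", "module_stats_eligible")

#' Write and read measurement tables (CSV)
#'
#' Long dialect: one row per specimen-module-side plus one summary row
#' per specimen (side = `"summary"`, module fields empty). Columns:
#' `specimen_id, tl_mm, tw_mm, n_modules_observed, amu_margin_mm,
#' module_index, side, mlm_mm, mlom_mm, mw_mm, module_stats_eligible`.
#' "." decimal, comma separator, UTF-8, mandatory header; numbers carry
#' full precision. Leading `#` comment lines carry tool version and seed
#' and are skipped on read. The reader also accepts a wide per-specimen
#' summary dialect (no module rows) and tolerates unrecognized extra
#' columns with a warning.
#'
#' @param records List of `measurement_record` objects.
#' @param path File path.
#' @param seed Optional seed recorded in the file header comment.
#' @return `read_measurements` returns a list of `measurement_record`
#'   objects; `write_measurements` returns `path` invisibly.
#' @export
write_measurements <- function(records, path, seed = NA) {
  records <- as_record_list(records)
  rows <- lapply(records, function(r) {
    summary_row <- data.frame(
      specimen_id = r$specimen_id, tl_mm = r$tl_mm, tw_mm = r$tw_mm,
      n_modules_observed = r$n_modules_observed,
      amu_margin_mm = r$amu_margin_mm,
      module_index = NA_integer_, side = "summary",
      mlm_mm = NA_real_, mlom_mm = NA_real_, mw_mm = NA_real_,
      module_stats_eligible = r$module_stats_eligible)
    if (nrow(r$modules) == 0L) return(summary_row)
    mod_rows <- data.frame(
      specimen_id = r$specimen_id, tl_mm = r$tl_mm, tw_mm = r$tw_mm,
      n_modules_observed = r$n_modules_observed,
      amu_margin_mm = r$amu_margin_mm,
      module_index = r$modules$module_index, side = r$modules$side,
      mlm_mm = r$modules$mlm_mm, mlom_mm = r$modules$mlom_mm,
      mw_mm = r$modules$mw_mm,
      module_stats_eligible = r$module_stats_eligible)
    rbind(summary_row, mod_rows)
  })
  tab <- do.call(rbind, rows)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# dickinsonia %s measurement CSV; seed=%s",
                     as.character(utils::packageVersion("dickinsonia")),
                     as.character(seed)), con)
  utils::write.table(format_numeric_df(tab), con, sep = ",", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

format_numeric_df <- function(df) {
  for (nm in names(df)) {
    if (is.numeric(df[[nm]]) && !is.integer(df[[nm]])) {
      df[[nm]] <- ifelse(is.na(df[[nm]]), NA,
                         sprintf("%.12g", df[[nm]]))
    }
  }
  df
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(c("specimen_id", "tl_mm", "tw_mm"), names(tab))
  if (length(missing)) {
    stop(sprintf("measurement CSV missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  extra <- setdiff(names(tab), measurement_columns)
  if (length(extra)) {
    warning(sprintf("unrecognized measurement column(s) ignored: %s",
                    paste(extra, collapse = ", ")), call. = FALSE)
  }
  wide <- !("module_index" %in% names(tab))
  lapply(split(tab, factor(tab$specimen_id, levels = unique(tab$specimen_id))),
         function(g) {
    if (wide) {
      mods <- data.frame(module_index = integer(), side = character(),
                         mlm_mm = numeric(), mlom_mm = numeric(),
                         mw_mm = numeric())
      head_row <- g[1L, ]
    } else {
      is_mod <- !is.na(g$module_index)
      mods <- data.frame(module_index = as.integer(g$module_index[is_mod]),
                         side = g$side[is_mod],
                         mlm_mm = as.numeric(g$mlm_mm[is_mod]),
                         mlom_mm = as.numeric(g$mlom_mm[is_mod]),
                         mw_mm = as.numeric(g$mw_mm[is_mod]))
      summary_idx <- which(!is_mod)
      head_row <- if (length(summary_idx)) g[summary_idx[1L], ] else g[1L, ]
    }
    n_obs <- head_row$n_modules_observed %||% NA_integer_
    if (is.null(n_obs) || is.na(n_obs)) {
      n_obs <- if (nrow(mods)) max(mods$module_index) else 0L
    }
    structure(
      list(specimen_id = head_row$specimen_id,
           tl_mm = as.numeric(head_row$tl_mm),
           tw_mm = as.numeric(head_row$tw_mm),
           n_modules_observed = as.integer(n_obs),
           n_modules_true = NA_integer_,
           amu_margin_mm = as.numeric(head_row$amu_margin_mm %||% NA_real_),
           measurable_fraction = NA_real_,
           module_stats_eligible =
             isTRUE(as.logical(head_row$module_stats_eligible %||% TRUE)),
           unmeasurable = FALSE,
           amu_convention = "arc",
           modules = mods),
      class = "measurement_record")
  }) |> unname()
}

#' Import an external measurement table with column mapping
#'
#' Reads a foreign CSV (for example a spreadsheet export of a published
#' measurement dataset) and maps user-specified column names onto the
#' package's measurement dialect. Only the mapped columns are used.
#'
#' @param path CSV file path.
#' @param column_map Named character vector mapping dialect names
#'   (e.g. `tl_mm`) to the file's column names. `specimen_id`, `tl_mm`
#'   and `tw_mm` are required; `n_modules_observed` and `amu_margin_mm`
#'   are optional.
#' @return List of wide-dialect `measurement_record` objects.
#' @export
read_external_measurements <- function(path, column_map) {
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                         check.names = FALSE)
  required <- c("specimen_id", "tl_mm", "tw_mm")
  missing_map <- setdiff(required, names(column_map))
  if (length(missing_map)) {
    stop(sprintf("column_map must map: %s",
                 paste(missing_map, collapse = ", ")), call. = FALSE)
  }
  absent <- setdiff(unname(column_map), names(tab))
  if (length(absent)) {
    stop(sprintf("mapped column(s) absent from file: %s",
                 paste(absent, collapse = ", ")), call. = FALSE)
  }
  get <- function(field) {
    if (field %in% names(column_map)) tab[[column_map[[field]]]] else NULL
  }
  n <- nrow(tab)
  ids <- as.character(get("specimen_id"))
  tls <- as.numeric(get("tl_mm"))
  tws <- as.numeric(get("tw_mm"))
  nmods <- get("n_modules_observed")
  amus <- get("amu_margin_mm")
  bad <- which(!is.finite(tls) | !is.finite(tws))
  if (length(bad)) {
    stop(sprintf("non-numeric size measurement at data row(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  lapply(seq_len(n), function(i) {
    structure(
      list(specimen_id = ids[i], tl_mm = tls[i], tw_mm = tws[i],
           n_modules_observed =
             if (is.null(nmods)) NA_integer_ else as.integer(nmods[i]),
           n_modules_true = NA_integer_,
           amu_margin_mm = if (is.null(amus)) NA_real_
                           else as.numeric(amus[i]),
           measurable_fraction = NA_real_,
           module_stats_eligible = FALSE,
           unmeasurable = FALSE, amu_convention = "unknown",
           modules = data.frame(module_index = integer(), side = character(),
                                mlm_mm = numeric(), mlom_mm = numeric(),
                                mw_mm = numeric())),
      class = "measurement_record")
  })
}

#' Render a specimen as SVG
#'
#' Deterministic vector drawing of the outline, midline, AMU (shaded
#' anterior cap), module boundary curves and medial paths; identical
#' input yields byte-identical output. The drawing is scaled to a fixed
#' canvas with the anterior to the right.
#'
#' @param s A `specimen`.
#' @param path Output file path.
#' @param width_px Canvas width in pixels.
#' @return `path`, invisibly.
#' @export
render_specimen_svg <- function(s, path, width_px = 640) {
  pts <- s$outline$points
  tl <- diff(range(pts[, 1L]))
  tw <- diff(range(pts[, 2L]))
  pad <- 0.05 * tl
  x0 <- min(pts[, 1L]) - pad
  y1 <- max(pts[, 2L]) + pad
  scale <- width_px / (tl + 2 * pad)
  height_px <- ceiling((tw + 2 * pad) * scale)
  px <- function(m) {
    cbind((m[, 1L] - x0) * scale, (y1 - m[, 2L]) * scale)
  }
  path_d <- function(m, close = FALSE) {
    p <- px(m)
    d <- paste0("M", paste(sprintf("%.3f,%.3f", p[, 1L], p[, 2L]),
                           collapse = " L"))
    if (close) d <- paste0(d, " Z")
    d
  }
  lines <- c(
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" width="%d" ',
                   'height="%d" viewBox="0 0 %d %d">'),
            as.integer(width_px), as.integer(height_px),
            as.integer(width_px), as.integer(height_px)),
    sprintf('<path d="%s" fill="#f4ead8" stroke="none"/>',
            path_d(pts, close = TRUE)))
  if (length(s$amu$arc_point_indices) >= 2L) {
    amu_pts <- pts[s$amu$arc_point_indices, , drop = FALSE]
    lines <- c(lines,
               sprintf('<path d="%s Z" fill="#d8b46e" stroke="none"/>',
                       path_d(amu_pts)))
  }
  lines <- c(lines,
             sprintf('<path d="%s" fill="none" stroke="#3a2d1a" stroke-width="1.5"/>',
                     path_d(rbind(pts, pts[1L, , drop = FALSE]))))
  if (s$n_modules_true > 0L) {
    mid <- rbind(
      c(s$generation$x_amu %||% max(pts[, 1L]), 0),
      pts[s$posterior_pole_index, , drop = FALSE])
    lines <- c(lines,
               sprintf('<path d="%s" fill="none" stroke="#3a2d1a" stroke-width="0.8"/>',
                       path_d(mid)))
    for (m in s$modules) {
      lines <- c(lines,
                 sprintf('<path d="%s" fill="none" stroke="#6b5230" stroke-width="0.8"/>',
                         path_d(m$boundary_curve)),
                 sprintf('<path d="%s" fill="none" stroke="#a58a5f" stroke-width="0.5" stroke-dasharray="3,2"/>',
                         path_d(m$medial_curve)))
    }
  }
  lines <- c(lines, "</svg>")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write a population summary as JSON
#'
#' Serializes a [summarize_population()] result (plus tool version and
#' seed metadata) as a JSON report. Missing values become `null`.
#'
#' @param summary A `population_summary`.
#' @param path Output file path.
#' @param seed Optional seed recorded in the report.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(summary, path, seed = NA) {
  out <- unclass(summary)
  out <- lapply(out, function(x) {
    if (inherits(x, "regression_result")) unclass(x) else x
  })
  out$tool <- list(
    name = "dickinsonia",
    version = as.character(utils::packageVersion("dickinsonia")),
    seed = seed)
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE,
                       na = "null", null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a flat key = value run configuration
#'
#' Parses a flat TOML-style `key = value` file naming [growth_params()]
#' and [taphonomy_params()] fields (comments with `#`; growth keys bare,
#' taphonomy keys as written). Unknown keys error.
#'
#' @param path Config file path.
#' @return List with `growth` and `taphonomy` parameter objects.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1L], collapse = "="),
                        character(1)))
  growth_names <- names(formals(growth_params))
  taph_names <- names(formals(taphonomy_params))
  unknown <- setdiff(keys, c(growth_names, taph_names))
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  parse_val <- function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  }
  g <- lapply(vals[keys %in% growth_names], parse_val)
  names(g) <- keys[keys %in% growth_names]
  t <- lapply(vals[keys %in% taph_names], parse_val)
  names(t) <- keys[keys %in% taph_names]
  list(growth = do.call(growth_params, g),
       taphonomy = do.call(taphonomy_params, t))
}
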