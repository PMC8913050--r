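#' Write / read kinematics as OpenSim-style motion text (.mot/.sto dialect)
#'
#' The format is a plain-text header (`name`, `nRows`, `nColumns`,
#' `endheader`) followed by tab-separated columns `time, knee_flexion,
#' knee_adduction, knee_rotation`. Angles are in degrees; the time column is
#' the cycle fraction 0.00-1.00 with one row per sample.
#'
#' @param kin A [generate_subject_kinematics()] result.
#' @param path Output file path (conventionally `.mot` or `.sto`).
#' @return `write_mot()` returns `path` invisibly; `read_mot()` returns a
#'   `gait_kinematics` object.
#' @export
write_mot <- function(kin, path) {
  stopifnot(inherits(kin, "gait_kinematics"))
  df <- as.data.frame(kin)
  con <- file(path, open = "wb") # binary mode: stable newlines across platforms
  on.exit(close(con))
  writeLines(c(
    paste0("name ", kin$subject_id),
    "version 1",
    paste0("nRows ", nrow(df)),
    "nColumns 4",
    "inDegrees yes",
    paste0("stance_fraction ", format(kin$stance_fraction, digits = 15)),
    "endheader",
    paste(c("time", "knee_flexion", "knee_adduction", "knee_rotation"),
      collapse = "\t"
    )
  ), con, sep = "\n")
  body <- apply(
    df[, c("time", "knee_flexion", "knee_adduction", "knee_rotation")],
    1L,
    function(r) paste(format(r, digits = 15, trim = TRUE), collapse = "\t")
  )
  writeLines(body, con, sep = "\n")
  invisible(path)
}

#' @rdname write_mot
#' @export
read_mot <- function(path) {
  if (!file.exists(path)) stop("motion file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  end <- which(lines == "endheader")
  if (length(end) != 1L) {
    stop(sprintf("%s: malformed motion file (missing endheader)", path),
      call. = FALSE
    )
  }
  header <- lines[seq_len(end - 1L)]
  get_field <- function(key, default = NULL) {
    hit <- grep(paste0("^", key, " "), header, value = TRUE)
    if (!length(hit)) return(default)
    sub(paste0("^", key, " "), "", hit[1])
  }
  name <- get_field("name", "subject")
  stance <- as.numeric(get_field("stance_fraction", "0.60"))
  n_rows <- as.integer(get_field("nRows"))
  col_line <- end + 1L
  cols <- strsplit(lines[col_line], "\t", fixed = TRUE)[[1]]
  want <- c("time", "knee_flexion", "knee_adduction", "knee_rotation")
  if (!all(want %in% cols)) {
    stop(sprintf(
      "%s: line %d: expected columns %s", path, col_line,
      paste(want, collapse = ", ")
    ), call. = FALSE)
  }
  body <- lines[(col_line + 1L):length(lines)]
  body <- body[nzchar(body)]
  if (!is.na(n_rows) && length(body) != n_rows) {
    stop(sprintf(
      "%s: header declares nRows %d but %d data rows found", path, n_rows,
      length(body)
    ), call. = FALSE)
  }
  mat <- matrix(NA_real_, nrow = length(body), ncol = length(cols))
  for (i in seq_along(body)) {
    parts <- suppressWarnings(as.numeric(strsplit(body[i], "\t", fixed = TRUE)[[1]]))
    if (length(parts) != length(cols) || any(is.na(parts))) {
      stop(sprintf("%s: line %d: malformed data row", path, col_line + i),
        call. = FALSE
      )
    }
    mat[i, ] <- parts
  }
  colnames(mat) <- cols
  kin <- structure(
    list(
      subject_id = name,
      n_points = nrow(mat),
      time = mat[, "time"],
      flexion = mat[, "knee_flexion"],
      adduction = mat[, "knee_adduction"],
      internal_rotation = mat[, "knee_rotation"],
      stance_fraction = stance
    ),
    class = "gait_kinematics"
  )
  validate_gait_kinematics(kin)
  kin
}

#' Write / read kinematics as plain CSV
#'
#' Same columns as the motion-text format: `time, knee_flexion,
#' knee_adduction, knee_rotation` plus a `subject_id` column.
#'
#' @inheritParams write_mot
#' @export
write_kinematics_csv <- function(kin, path) {
  stopifnot(inherits(kin, "gait_kinematics"))
  utils::write.csv(as.data.frame(kin), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kinematics_csv
#' @param stance_fraction Stance fraction to attach (CSV carries no header
#'   metadata).
#' @export
read_kinematics_csv <- function(path, stance_fraction = 0.60) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  want <- c("subject_id", "time", "knee_flexion", "knee_adduction", "knee_rotation")
  if (!all(want %in% names(df))) {
    stop(sprintf("%s: expected columns %s", path, paste(want, collapse = ", ")),
      call. = FALSE
    )
  }
  kin <- structure(
    list(
      subject_id = as.character(df$subject_id[1]),
      n_points = nrow(df),
      time = df$time,
      flexion = df$knee_flexion,
      adduction = df$knee_adduction,
      internal_rotation = df$knee_rotation,
      stance_fraction = stance_fraction
    ),
    class = "gait_kinematics"
  )
  validate_gait_kinematics(kin)
  kin
}

#' Write the tidy sweep table and run manifest
#'
#' The sweep CSV has columns `subject_id, direction, magnitude_mm, cycle_pct,
#' force_N`; the JSON manifest records the configuration, seeds, per-subject
#' scales and package version for provenance.
#'
#' @param sweep An [run_sweep()] result.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_sweep <- function(sweep, out_dir) {
  stopifnot(inherits(sweep, "acl_sweep"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  csv_path <- file.path(out_dir, "force_curves.csv")
  df <- as.data.frame(sweep)
  utils::write.csv(df, csv_path, row.names = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("acltis")),
    n_subjects = length(sweep$subject_ids),
    n_conditions = nrow(sweep$grid),
    subject_seeds = stats::setNames(
      vapply(
        sweep$curves[match(sweep$subject_ids,
          vapply(sweep$curves, `[[`, character(1), "subject_id")
        )],
        `[[`, integer(1), "rng_seed"
      ),
      sweep$subject_ids
    ),
    uniform_scales = stats::setNames(
      vapply(
        sweep$curves[match(sweep$subject_ids,
          vapply(sweep$curves, `[[`, character(1), "subject_id")
        )],
        `[[`, numeric(1), "uniform_scale"
      ),
      sweep$subject_ids
    ),
    config = unclass(sweep$config),
    config_hash = unname(tools::md5sum(local({
      tmp <- tempfile()
      yaml::write_yaml(unclass(sweep$config), tmp, precision = 15)
      tmp
    })))
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path,
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(c(csv = csv_path, manifest = manifest_path))
}

#' Read a tidy sweep CSV back into an `acl_sweep` object
#'
#' Validates that the table is a complete subject-by-condition cross product
#' of 101-point curves; incomplete tables raise an error listing the missing
#' or short cells.
#'
#' @param path Path to `force_curves.csv` as written by [write_sweep()].
#' @param config Configuration used for downstream reporting.
#' @return An `acl_sweep` object (force traces only: lengths and strains are
#'   not stored in the CSV).
#' @export
read_sweep <- function(path, config = default_config()) {
  if (!file.exists(path)) stop("sweep CSV not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  want <- c("subject_id", "direction", "magnitude_mm", "cycle_pct", "force_N")
  if (!all(want %in% names(df))) {
    stop(sprintf("%s: expected columns %s", path, paste(want, collapse = ", ")),
      call. = FALSE
    )
  }
  subjects <- unique(df$subject_id)
  key <- interaction(df$subject_id, df$direction, df$magnitude_mm, drop = TRUE)
  pieces <- split(df, key)
  bad <- names(pieces)[vapply(pieces, nrow, integer(1)) != 101L]
  if (length(bad)) {
    stop("sweep CSV has cells without 101 samples: ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  grid_df <- unique(df[, c("direction", "magnitude_mm")])
  convention <- frame_convention(config$side)
  spec0 <- config_ligament_spec(config)
  grid <- make_tis_grid(spec0$tibial_insertion, convention,
    magnitudes_mm = config$grid_magnitudes_mm
  )
  stance <- config$landmarks$stance_fraction
  curves <- list()
  for (sid in subjects) {
    for (g in seq_len(nrow(grid))) {
      cell <- df[df$subject_id == sid & df$direction == grid$direction[g] &
        df$magnitude_mm == grid$magnitude_mm[g], , drop = FALSE]
      if (nrow(cell) == 0L) next # completeness checked downstream
      cell <- cell[order(cell$cycle_pct), ]
      curves[[length(curves) + 1L]] <- structure(
        list(
          subject_id = sid,
          direction = grid$direction[g],
          magnitude_mm = grid$magnitude_mm[g],
          time = cell$cycle_pct / 100,
          length = NULL,
          strain = NULL,
          force = cell$force_N,
          all_slack = all(cell$force_N == 0),
          stance_fraction = stance
        ),
        class = "force_curve"
      )
    }
  }
  found <- unique(paste(grid_df$direction, grid_df$magnitude_mm))
  expected <- paste(grid$direction, grid$magnitude_mm)
  if (!all(found %in% expected)) {
    stop("sweep CSV contains conditions outside the configured grid: ",
      paste(setdiff(found, expected), collapse = ", "),
      call. = FALSE
    )
  }
  structure(
    list(
      curves = curves,
      grid = grid,
      subject_ids = subjects,
      stance_fraction = stance,
      config = config
    ),
    class = "acl_sweep"
  )
}
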