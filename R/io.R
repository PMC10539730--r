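# ---- flat key = value experiment configs ------------------------------

config_keys <- list(
  required = c("larmor_mhz", "delta_a_ppm", "r1a_per_s", "r2a_per_s",
               "omega1_rad_s", "offset_ppm", "tsat_s"),
  optional = c("gamma_bar_mhz_t", "gamma_sign", "m0a",
               "d_m", "gsat_mt_m", "gacq_mt_m", "n_positions",
               "noise_sigma", "off_scale"),
  pool = c("f", "kout_per_s", "delta_b_ppm", "r1b_per_s", "r2b_per_s")
)

#' Read and validate a flat experiment config
#'
#' One experiment per file, `key = value` lines, `#` comments. Units
#' are encoded in the key names (`omega1_rad_s`, `gsat_mt_m`, `tsat_s`,
#' `delta_a_ppm`, ...), which is the cheapest reliable guard against
#' rad/Hz/ppm mix-ups. Bound pools are numbered suffixes: `f_1`,
#' `kout_1_per_s`, `delta_b_1_ppm` (optionally `r1b_1_per_s`,
#' `r2b_1_per_s`), and so on. Unknown keys are rejected by name;
#' non-physical values are rejected by the domain constructors.
#'
#' @param path Path to the config file.
#' @return An object of class `experiment_config` (a named list of
#'   numeric values plus a `pools` tibble).
#' @seealso [config_system()], [config_saturation()], [config_ufz()],
#'   [preset_config()]
#' @export
read_config <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("config file is empty: ", path)
  bad <- !grepl("^[A-Za-z0-9_]+\\s*=\\s*[-+0-9.eE]+$", lines)
  if (any(bad)) {
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  }
  keys <- trimws(sub("=.*$", "", lines))
  vals <- as.numeric(trimws(sub("^[^=]*=", "", lines)))
  if (anyDuplicated(keys)) {
    stop("duplicate config key(s): ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  }
  named <- stats::setNames(as.list(vals), keys)

  pool_rx <- "^(f|kout|delta_b|r1b|r2b)_([0-9]+)(_per_s|_ppm)?$"
  is_pool <- grepl(pool_rx, keys)
  scalar <- keys[!is_pool]
  known <- c(config_keys$required, config_keys$optional)
  unknown <- setdiff(scalar, known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  missing <- setdiff(config_keys$required, scalar)
  if (length(missing)) {
    stop("missing required config key(s): ",
         paste(missing, collapse = ", "))
  }

  pool_ids <- sort(unique(as.integer(sub(pool_rx, "\\2", keys[is_pool]))))
  pools <- purrr::map_dfr(pool_ids, function(j) {
    gk <- function(stem, suffix = "") {
      k <- paste0(stem, "_", j, suffix)
      if (k %in% keys) named[[k]] else NA_real_
    }
    row <- tibble::tibble(
      pool = j,
      f = gk("f"),
      k_out = gk("kout", "_per_s"),
      delta_ppm = gk("delta_b", "_ppm"),
      r1 = gk("r1b", "_per_s"),
      r2 = gk("r2b", "_per_s")
    )
    core <- c("f", "k_out", "delta_ppm")
    if (any(is.na(row[core]))) {
      stop("pool ", j, " incomplete: needs f_", j, ", kout_", j,
           "_per_s, delta_b_", j, "_ppm")
    }
    row
  })

  cfg <- named[scalar]
  cfg$pools <- pools

  check <- function(key, ok, what) {
    if (!is.null(cfg[[key]]) && !ok(cfg[[key]])) {
      stop("non-physical value for ", key, ": must be ", what)
    }
  }
  check("larmor_mhz", function(x) x > 0, "positive")
  check("gamma_bar_mhz_t", function(x) x > 0, "positive")
  check("r1a_per_s", function(x) x >= 0, "non-negative")
  check("r2a_per_s", function(x) x >= 0, "non-negative")
  check("omega1_rad_s", function(x) x >= 0, "non-negative")
  check("tsat_s", function(x) x >= 0, "non-negative")
  check("m0a", function(x) x > 0, "positive")
  check("d_m", function(x) x > 0, "positive")
  check("gacq_mt_m", function(x) x != 0, "non-zero")
  check("n_positions", function(x) x >= 32, "at least 32")
  check("noise_sigma", function(x) x >= 0, "non-negative")
  check("off_scale", function(x) x > 0, "positive")
  if (nrow(pools)) {
    if (any(pools$f <= 0 | pools$f >= 1)) {
      stop("non-physical value for pool f: must be in (0, 1)")
    }
    if (any(pools$k_out <= 0)) {
      stop("non-physical value for pool k_out: must be positive")
    }
    if (any(!is.na(pools$r1) & pools$r1 < 0) ||
        any(!is.na(pools$r2) & pools$r2 < 0)) {
      stop("non-physical value for pool relaxation: must be non-negative")
    }
  }
  structure(cfg, class = "experiment_config")
}

#' Build domain objects from a config
#'
#' @param cfg An `experiment_config` from [read_config()].
#' @param rng_seed Optional noise seed for the UFZ experiment.
#' @return [config_system()] an [exchange_system()];
#'   [config_saturation()] a [saturation_scheme()]; [config_ufz()] a
#'   [ufz_experiment()] (requires the gradient/geometry keys).
#' @export
config_system <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  field <- field_config(
    cfg$larmor_mhz,
    gamma_bar_mhz_t = cfg$gamma_bar_mhz_t %||% 11.79,
    gamma_sign = cfg$gamma_sign %||% -1
  )
  free <- free_pool(cfg$delta_a_ppm, cfg$r1a_per_s, cfg$r2a_per_s,
                    m0 = cfg$m0a %||% 1)
  bound <- purrr::pmap(cfg$pools, function(pool, f, k_out, delta_ppm, r1, r2) {
    bound_pool(f, k_out, delta_ppm,
               r1 = if (is.na(r1)) cfg$r1a_per_s else r1,
               r2 = if (is.na(r2)) 1 else r2)
  })
  exchange_system(field, free, bound)
}

#' @rdname config_system
#' @export
config_saturation <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  saturation_scheme(cfg$omega1_rad_s, cfg$offset_ppm, cfg$tsat_s)
}

#' @rdname config_system
#' @export
config_ufz <- function(cfg, rng_seed = NULL) {
  stopifnot(inherits(cfg, "experiment_config"))
  need <- c("gsat_mt_m", "gacq_mt_m")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) {
    stop("config lacks UFZ key(s): ", paste(miss, collapse = ", "))
  }
  ufz_experiment(
    system = config_system(cfg),
    sat = config_saturation(cfg),
    geometry = tube_geometry(cfg$d_m %||% 0.0043),
    gradients = gradient_scheme(cfg$gsat_mt_m / 1000, cfg$gacq_mt_m / 1000),
    n_positions = as.integer(cfg$n_positions %||% 512),
    noise_sigma = cfg$noise_sigma %||% 0,
    off_scale = cfg$off_scale %||% 1,
    rng_seed = rng_seed
  )
}

#' Bundled example configs
#'
#' Three presets covering the scenarios the package is built around:
#' `"zscan-11p7T"` (high-field single cryptophane, strong saturation,
#' 1 s), `"zscan-1T"` (benchtop single cryptophane, weak saturation,
#' 3 s) and `"mixture-1T"` (benchtop two-cryptophane mixture with the
#' UFZ gradient keys).
#'
#' @param name Preset name; `NULL` lists the available names.
#' @return Path to the config file, or a character vector of names.
#' @examples
#' cfg <- read_config(preset_config("zscan-1T"))
#' cfg$omega1_rad_s
#' @export
preset_config <- function(name = NULL) {
  dir <- system.file("extdata", "configs", package = "hypercest")
  avail <- sub("\\.cfg$", "", list.files(dir, pattern = "\\.cfg$"))
  if (is.null(name)) return(avail)
  path <- file.path(dir, paste0(name, ".cfg"))
  if (!file.exists(path)) {
    stop("unknown preset '", name, "'; available: ",
         paste(avail, collapse = ", "))
  }
  path
}

# ---- trace I/O: CSV and minimal JCAMP-DX ------------------------------

axis_candidates <- c("offset_ppm", "position_m", "apparent_ppm")

trace_axis_column <- function(trace) {
  ax <- intersect(axis_candidates, names(trace))
  if (!length(ax)) {
    stop("trace must contain one of: ",
         paste(axis_candidates, collapse = ", "))
  }
  ax[1]
}

#' Write a 1-D trace to CSV or JCAMP-DX
#'
#' CSV keeps every column at full double precision (17 significant
#' digits), so a write/read cycle is value-exact. JCAMP-DX output is a
#' minimal single-block record (AFFN `(XY..XY)` pairs, one intensity
#' column) sufficient for interchange with spectroscopy software; the
#' axis kind is recorded so it survives the round trip.
#'
#' @param trace A tibble with an axis column (`offset_ppm`,
#'   `position_m` or `apparent_ppm`) and at least one intensity column.
#' @param path Output file path.
#' @param format `"csv"` or `"jcamp"`.
#' @param title Title string for the JCAMP header.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, format = c("csv", "jcamp"),
                        title = "hypercest trace") {
  format <- match.arg(format)
  if (!nrow(trace)) stop("refusing to write an empty trace")
  ax <- trace_axis_column(trace)
  if (format == "csv") {
    num <- vapply(trace, is.numeric, logical(1))
    cols <- purrr::map(trace, function(col) {
      if (is.numeric(col)) sprintf("%.17g", col) else as.character(col)
    })
    lines <- c(paste(names(trace), collapse = ","),
               do.call(paste, c(cols, sep = ",")))
    writeLines(lines, path)
  } else {
    ycols <- setdiff(names(trace)[vapply(trace, is.numeric, logical(1))], ax)
    if (!length(ycols)) stop("trace has no intensity column")
    ycol <- ycols[1]
    x <- trace[[ax]]
    y <- trace[[ycol]]
    xunits <- switch(ax, offset_ppm = "PPM", apparent_ppm = "PPM",
                     position_m = "METERS")
    header <- c(
      sprintf("##TITLE=%s", title),
      "##JCAMP-DX=4.24",
      "##DATA TYPE=NMR SPECTRUM",
      "##ORIGIN=hypercest",
      "##OWNER=",
      sprintf("##XUNITS=%s", xunits),
      "##YUNITS=ARBITRARY UNITS",
      sprintf("##$AXISKIND=%s", ax),
      sprintf("##$YCOLUMN=%s", ycol),
      sprintf("##NPOINTS=%d", length(x)),
      sprintf("##FIRSTX=%.10g", x[1]),
      sprintf("##LASTX=%.10g", x[length(x)]),
      sprintf("##MAXY=%.10g", max(y)),
      sprintf("##MINY=%.10g", min(y)),
      "##XYPOINTS=(XY..XY)"
    )
    body <- sprintf("%.10g, %.10g", x, y)
    writeLines(c(header, body, "##END="), path)
  }
  invisible(path)
}

#' Read a 1-D trace written by [write_trace()]
#'
#' The dialect is detected from the content (a leading `##TITLE` label
#' means JCAMP-DX, otherwise a header line plus CSV rows). The axis
#' kind is restored from the column name (CSV) or the recorded
#' axis-kind label / x-units (JCAMP-DX).
#'
#' @param path Path to the file.
#' @return A tibble with the axis column and intensity column(s).
#' @export
read_trace <- function(path) {
  stopifnot(file.exists(path))
  first <- readLines(path, n = 1, warn = FALSE)
  if (!length(first)) stop("empty trace file: ", path)
  if (grepl("^##TITLE", first)) {
    return(read_trace_jcamp(path))
  }
  header <- strsplit(first, ",", fixed = TRUE)[[1]]
  if (!any(axis_candidates %in% header)) {
    stop("missing or unrecognized header in ", path,
         ": expected one of ", paste(axis_candidates, collapse = ", "))
  }
  df <- utils::read.csv(path, check.names = FALSE)
  bad <- which(!vapply(df, is.numeric, logical(1)))
  if (length(bad)) {
    stop("non-numeric content in column(s) ",
         paste(names(df)[bad], collapse = ", "), " of ", path)
  }
  tibble::as_tibble(df)
}

read_trace_jcamp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  grab <- function(label) {
    hit <- grep(paste0("^##\\$?", label, "="), lines, value = TRUE)
    if (!length(hit)) return(NULL)
    trimws(sub("^[^=]*=", "", hit[1]))
  }
  axis <- grab("AXISKIND")
  if (is.null(axis)) {
    xunits <- grab("XUNITS") %||% "PPM"
    axis <- if (identical(xunits, "METERS")) "position_m" else "offset_ppm"
  }
  ycol <- grab("YCOLUMN") %||% "intensity"
  start <- grep("^##XYPOINTS", lines)
  if (!length(start)) stop("no XYPOINTS table in ", path)
  end <- grep("^##END", lines)
  end <- if (length(end)) end[1] else length(lines) + 1
  body <- lines[(start + 1):(end - 1)]
  body <- body[nzchar(trimws(body))]
  parts <- strsplit(body, ",")
  bad <- which(vapply(parts, length, integer(1)) != 2)
  if (length(bad)) {
    stop("malformed XYPOINTS pair at line ", start + bad[1], " of ", path)
  }
  x <- as.numeric(vapply(parts, `[[`, character(1), 1))
  y <- as.numeric(vapply(parts, `[[`, character(1), 2))
  if (anyNA(x) || anyNA(y)) {
    stop("non-numeric XYPOINTS content in ", path)
  }
  n_declared <- as.integer(grab("NPOINTS") %||% length(x))
  if (n_declared != length(x)) {
    stop("NPOINTS (", n_declared, ") disagrees with table length (",
         length(x), ") in ", path)
  }
  out <- tibble::tibble(x, y)
  names(out) <- c(axis, ycol)
  out
}

# ---- synthetic UFZ fixtures -------------------------------------------

#' Generate noisy UFZ fixture traces with ground truth
#'
#' Writes `n` replicate UFZ profile CSVs (columns `position_m`,
#' `offset_ppm`, `on`, `off`), each with an independent noise seed
#' derived from `base_seed`, plus one `ground-truth.cfg` sidecar
#' recording the generating parameters in the flat config format. Used
#' by the parameter-recovery studies, and exposed so users can rehearse
#' a fit pipeline on data with known answers before touching real
#' spectra.
#'
#' @param dir Output directory (created if needed).
#' @param experiment A [ufz_experiment()]; its `rng_seed` is ignored in
#'   favour of the per-replicate seeds.
#' @param n Number of replicates.
#' @param base_seed Integer; replicate i uses seed `base_seed + i`.
#' @return A tibble with columns `replicate`, `seed`, `path`,
#'   invisibly.
#' @export
make_ufz_fixtures <- function(dir, experiment, n = 20, base_seed = 1) {
  stopifnot(inherits(experiment, "ufz_experiment"), n >= 1)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sys <- experiment$system
  truth <- c(
    sprintf("larmor_mhz = %.10g", sys$field$larmor_mhz),
    sprintf("gamma_bar_mhz_t = %.10g", sys$field$gamma_bar_mhz_t),
    sprintf("gamma_sign = %d", sys$field$gamma_sign),
    sprintf("delta_a_ppm = %.10g", sys$free$delta_ppm),
    sprintf("r1a_per_s = %.10g", sys$free$r1),
    sprintf("r2a_per_s = %.10g", sys$free$r2),
    sprintf("omega1_rad_s = %.10g", experiment$sat$omega1),
    sprintf("offset_ppm = %.10g", experiment$sat$offset_ppm),
    sprintf("tsat_s = %.10g", experiment$sat$t_sat),
    sprintf("d_m = %.10g", experiment$geometry$inner_diameter_m),
    sprintf("gsat_mt_m = %.10g", experiment$gradients$g_sat * 1000),
    sprintf("gacq_mt_m = %.10g", experiment$gradients$g_acq * 1000),
    sprintf("n_positions = %d", experiment$n_positions),
    sprintf("noise_sigma = %.10g", experiment$noise_sigma),
    sprintf("off_scale = %.10g", experiment$off_scale),
    unlist(purrr::imap(sys$bound, function(b, j) {
      c(sprintf("f_%d = %.10g", j, b$f),
        sprintf("kout_%d_per_s = %.10g", j, b$k_out),
        sprintf("delta_b_%d_ppm = %.10g", j, b$delta_ppm),
        sprintf("r1b_%d_per_s = %.10g", j, b$r1),
        sprintf("r2b_%d_per_s = %.10g", j, b$r2))
    }))
  )
  writeLines(truth, file.path(dir, "ground-truth.cfg"))
  out <- purrr::map_dfr(seq_len(n), function(i) {
    seed <- base_seed + i
    exp_i <- experiment
    exp_i$rng_seed <- seed
    prof <- simulate_profiles(exp_i)
    path <- file.path(dir, sprintf("ufz-%03d.csv", i))
    write_trace(prof, path, format = "csv")
    tibble::tibble(replicate = i, seed = seed, path = path)
  })
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
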