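## File I/O: columnar TSV for per-frame series, OpenDX scalar fields for
## potential grids, YAML for run configuration.

#' Write a per-frame series to a headered TSV file
#'
#' Tab-separated columnar format shared by atom tracks and energy-gap
#' series: comment header lines (`# key: value`) declaring `kind`
#' (`atom_track` or `energy_gap`), `label`, `units`, `state`, `v_mp` and
#' `seed`, followed by a `frame`/`value` table. The format round-trips
#' losslessly at full double precision.
#'
#' @param series Tibble with a `frame` column and a `z` (track) or `gap`
#'   (energy gap) column; single label per file.
#' @param path Output file path.
#' @param label Series label (atom label, or e.g. `"gap"`); inferred from a
#'   `label` column if present.
#' @param seed Seed recorded in the header (provenance only), or `NA`.
#' @return `path`, invisibly.
#' @export
write_track_tsv <- function(series, path, label = NULL, seed = NA) {
  has <- function(col) col %in% names(series)
  kind <- if (has("z")) "atom_track" else if (has("gap")) "energy_gap" else NULL
  if (is.null(kind) || !has("frame")) {
    abort_anepps("`series` must have a `frame` column and a `z` or `gap` column.",
                 "bad_series")
  }
  value <- if (kind == "atom_track") series$z else series$gap
  label <- label %||%
    (if (has("label")) unique(series$label)) %||%
    (if (kind == "energy_gap") "gap")
  if (length(label) != 1L) {
    abort_anepps("One label per file; split multi-label tracks first.",
                 "bad_series")
  }
  units <- if (kind == "atom_track") "angstrom" else "kcal/mol"
  meta1 <- function(col) {
    if (has(col)) format(unique(series[[col]])[1]) else "NA"
  }
  hdr <- c(
    sprintf("# kind: %s", kind),
    sprintf("# label: %s", label),
    sprintf("# units: %s", units),
    sprintf("# state: %s", meta1("state")),
    sprintf("# v_mp: %s", meta1("v_mp")),
    sprintf("# seed: %s", format(seed))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("frame\tvalue", con)
  writeLines(paste(series$frame, sprintf("%.17g", value), sep = "\t"), con)
  invisible(path)
}

parse_tsv_header <- function(lines) {
  hdr <- grep("^#", lines, value = TRUE)
  kv <- regmatches(hdr, regexec("^#\\s*([^:]+):\\s*(.*)$", hdr))
  keys <- vapply(kv, function(m) if (length(m) == 3L) trimws(m[2]) else NA_character_, "")
  vals <- vapply(kv, function(m) if (length(m) == 3L) trimws(m[3]) else NA_character_, "")
  setNames(as.list(vals), keys)
}

#' Read a per-frame series TSV written by [write_track_tsv()]
#'
#' Validates the header contract and the frame index invariant; malformed
#' files are rejected with a specific error (missing header, empty data
#' section, non-numeric rows, non-increasing frame indices).
#'
#' @param path File path.
#' @return Tibble with columns `frame` plus `z` (atom track) or `gap`
#'   (energy gap), and `label`, `state`, `v_mp` columns from the header.
#' @export
read_track_tsv <- function(path) {
  if (!file.exists(path)) {
    abort_anepps(sprintf("File not found: %s", path), "missing_file")
  }
  lines <- readLines(path)
  meta <- parse_tsv_header(lines)
  if (is.null(meta$kind) || !meta$kind %in% c("atom_track", "energy_gap")) {
    abort_anepps(
      sprintf("%s: missing or invalid header (need `# kind: atom_track|energy_gap`).", path),
      "bad_header"
    )
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L || body[1] != "frame\tvalue") {
    abort_anepps(sprintf("%s: missing `frame\\tvalue` column header.", path),
                 "bad_header")
  }
  body <- body[-1]
  if (length(body) == 0L) {
    abort_anepps(sprintf("%s: no frames in data section.", path), "no_frames")
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    abort_anepps(sprintf("%s: malformed data rows (expected 2 tab-separated fields).", path),
                 "bad_rows")
  }
  m <- do.call(rbind, parts)
  frame <- suppressWarnings(as.numeric(m[, 1]))
  value <- suppressWarnings(as.numeric(m[, 2]))
  if (any(is.na(frame)) || any(is.na(value))) {
    abort_anepps(sprintf("%s: non-numeric data rows.", path), "bad_rows")
  }
  if (any(diff(frame) <= 0)) {
    abort_anepps(
      sprintf("%s: frame indices must be strictly increasing (shuffled or duplicate frames).", path),
      "bad_frames"
    )
  }
  out <- tibble(frame = as.integer(frame))
  if (meta$kind == "atom_track") out$z <- value else out$gap <- value
  out$label <- meta$label %||% NA_character_
  out$state <- meta$state %||% NA_character_
  out$v_mp <- suppressWarnings(as.numeric(meta$v_mp %||% NA))
  out
}

#' Write a potential grid as an OpenDX scalar field
#'
#' Plain-text OpenDX "regular positions, regular connections" scalar field,
#' the common interchange format for volumetric electrostatic maps. Values
#' are written in mV (noted in a comment), three per line, with the z index
#' varying fastest as the format requires.
#'
#' @param grid A [potential_grid].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dx_grid <- function(grid, path) {
  stopifnot(inherits(grid, "potential_grid"))
  n <- dim(grid$values)
  vals <- as.vector(aperm(grid$values, c(3, 2, 1)))  # z fastest
  ntot <- length(vals)
  fmt <- sprintf("%.17g", vals)
  pad <- (-ntot) %% 3
  if (pad) fmt <- c(fmt, rep("", pad))
  rows <- matrix(fmt, ncol = 3, byrow = TRUE)
  data_lines <- trimws(apply(rows, 1, paste, collapse = " "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# OpenDX scalar field: electrostatic potential, units mV",
    sprintf("object 1 class gridpositions counts %d %d %d", n[1], n[2], n[3]),
    sprintf("origin %.17g %.17g %.17g",
            grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.17g 0 0", grid$spacing[1]),
    sprintf("delta 0 %.17g 0", grid$spacing[2]),
    sprintf("delta 0 0 %.17g", grid$spacing[3]),
    sprintf("object 2 class gridconnections counts %d %d %d",
            n[1], n[2], n[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            ntot)
  ), con)
  writeLines(data_lines, con)
  writeLines(c(
    'attribute "dep" string "positions"',
    'object "regular positions regular connections" class field',
    'component "positions" value 1',
    'component "connections" value 2',
    'component "data" value 3'
  ), con)
  invisible(path)
}

#' Read an OpenDX scalar field into a potential grid
#'
#' Parses the regular-grid OpenDX dialect written by [write_dx_grid()] (and
#' by common MD electrostatics tools). Orthogonal axis-aligned deltas are
#' required; counts inconsistent with the number of data items are
#' rejected.
#'
#' @param path File path.
#' @return A [potential_grid].
#' @export
read_dx_grid <- function(path) {
  if (!file.exists(path)) {
    abort_anepps(sprintf("File not found: %s", path), "missing_file")
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  gp <- grep("class gridpositions counts", lines, value = TRUE)[1]
  if (is.na(gp)) {
    abort_anepps(sprintf("%s: no `gridpositions` object found.", path),
                 "bad_dx")
  }
  counts <- as.integer(strsplit(trimws(sub(".*counts", "", gp)), "\\s+")[[1]])
  if (length(counts) != 3L || any(is.na(counts)) || any(counts < 1L)) {
    abort_anepps(sprintf("%s: malformed grid counts.", path), "bad_dx")
  }
  org_line <- grep("^\\s*origin", lines, value = TRUE)[1]
  origin <- as.numeric(strsplit(trimws(sub("origin", "", org_line)), "\\s+")[[1]])
  delta_lines <- grep("^\\s*delta", lines, value = TRUE)
  if (length(delta_lines) != 3L || length(origin) != 3L || any(is.na(origin))) {
    abort_anepps(sprintf("%s: need an origin and three delta lines.", path),
                 "bad_dx")
  }
  deltas <- t(vapply(delta_lines, function(l) {
    as.numeric(strsplit(trimws(sub("delta", "", l)), "\\s+")[[1]])
  }, numeric(3)))
  if (any(abs(deltas[upper.tri(deltas) | lower.tri(deltas)]) > 0)) {
    abort_anepps(
      sprintf("%s: non-orthogonal deltas are not supported.", path),
      "bad_dx"
    )
  }
  spacing <- diag(deltas)
  items_line <- grep("data follows", lines)[1]
  if (is.na(items_line)) {
    abort_anepps(sprintf("%s: no data section.", path), "bad_dx")
  }
  n_items <- as.integer(sub(".*items\\s+(\\d+)\\s+data follows.*", "\\1",
                            lines[items_line]))
  tail_start <- grep("^\\s*(attribute|object\\s+\")", lines)
  tail_start <- tail_start[tail_start > items_line]
  data_end <- if (length(tail_start)) min(tail_start) - 1L else length(lines)
  vals <- suppressWarnings(
    as.numeric(unlist(strsplit(trimws(lines[(items_line + 1L):data_end]),
                               "\\s+")))
  )
  vals <- vals[!is.na(vals)]
  if (length(vals) != n_items || n_items != prod(counts)) {
    abort_anepps(
      sprintf("%s: data item count (%d) disagrees with declared counts (%d expected).",
              path, length(vals), prod(counts)),
      "bad_dx"
    )
  }
  arr <- aperm(array(vals, dim = rev(counts)), c(3, 2, 1))
  potential_grid(arr, origin, spacing)
}

#' Write a potential-fraction profile as a two-column TSV
#' @param profile Tibble with `z`, `f`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  write.table(profile[c("z", "f")], path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}
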