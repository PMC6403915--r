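#' Read a degradation dataset from CSV
#'
#' Expects a header with at least \code{time_days} and \code{Mn_g_mol};
#' optional \code{Mw_g_mol} and \code{PD} columns are picked up, any other
#' columns are preserved in the metadata. Units are fixed in the column
#' names to prevent silent unit drift.
#'
#' @param path CSV file path.
#' @param dose_label label for the dataset; defaults to the file name.
#' @return a \code{degradation_dataset}.
#' @export
read_dataset <- function(path, dose_label = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("time_days", "Mn_g_mol")) {
    if (!col %in% names(df))
      stop("missing required column '", col, "' in ", path, call. = FALSE)
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))
      stop("non-numeric '", col, "' at row(s) ",
           paste(bad, collapse = ", "), " of ", path, call. = FALSE)
    }
  }
  extra <- setdiff(names(df), c("time_days", "Mn_g_mol", "Mw_g_mol", "PD"))
  degradation_dataset(
    df$time_days, df$Mn_g_mol,
    dose_label = if (is.null(dose_label)) basename(path) else dose_label,
    Mw = if ("Mw_g_mol" %in% names(df)) df$Mw_g_mol else NULL,
    PD = if ("PD" %in% names(df)) df$PD else NULL,
    metadata = if (length(extra)) df[extra] else list())
}

# fixed-precision number formatting so rewritten files are byte-identical
.fmt_num <- function(x) sprintf("%.10g", x)

#' Write a degradation dataset to CSV
#'
#' Columns \code{time_days}, \code{Mn_g_mol} and, when present,
#' \code{Mw_g_mol} and \code{PD}. Values are written with 10 significant
#' digits so that a write/read round trip preserves them exactly and
#' regeneration is byte-identical.
#'
#' @param data a \code{degradation_dataset}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_dataset <- function(data, path) {
  stopifnot(inherits(data, "degradation_dataset"))
  df <- data.frame(time_days = .fmt_num(data$times_days),
                   Mn_g_mol = .fmt_num(data$Mn))
  if (!is.null(data$Mw)) df$Mw_g_mol <- .fmt_num(data$Mw)
  if (!is.null(data$PD)) df$PD <- .fmt_num(data$PD)
  utils::write.table(df, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write a simulated trajectory to CSV
#'
#' Device-average properties per output time, columns \code{time_days},
#' \code{Mn_g_mol}, \code{Mw_g_mol}, \code{PD}. A configuration echo (the
#' resolved parameter set and package version) is written alongside as
#' \code{<path>.config.txt} unless \code{config_echo = FALSE}.
#'
#' @param traj a \code{trajectory} from [integrate_film()].
#' @param path output CSV path.
#' @param config_echo write the companion configuration file.
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(traj, path, config_echo = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  df <- as.data.frame(traj)
  df[] <- lapply(df, .fmt_num)
  utils::write.table(df, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  if (config_echo) {
    p <- traj$params
    lines <- c(
      sprintf("polyscission %s",
              as.character(utils::packageVersion("polyscission"))),
      sprintf("well_mixed: %s", traj$well_mixed),
      sprintf("%s: %.10g", names(unclass(p)), unlist(unclass(p))))
    writeLines(lines, paste0(path, ".config.txt"))
  }
  invisible(path)
}

.CONFIG_KEYS <- c("kd", "DM0", "Dolig0", "DW0", "Mmon", "rho_pol",
                  "CW_surface", "Mn_ref", "film_thickness_um", "n_nodes")

#' Load model configuration from a YAML file
#'
#' Reads a flat YAML mapping and returns a fully populated parameter set
#' and grid. Keys not given fall back to the reference thin-film defaults
#' (55 micrometre film, Mmon 90.08 g mol^-1, density 1.2 g cm^-3, pristine
#' diffusivities 1e-10 / 1e-10 / 1e-8 cm^2 s^-1 for monomer / oligomer /
#' water). Unknown keys are an error, so typos cannot silently revert a
#' value to its default.
#'
#' @param path YAML file, or NULL for all defaults.
#' @param quiet suppress the message listing defaulted keys.
#' @return list with elements \code{params} (a \code{model_params}) and
#'   \code{grid} (a \code{grid_spec}).
#' @export
load_config <- function(path = NULL, quiet = FALSE) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  unknown <- setdiff(names(cfg), .CONFIG_KEYS)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  defaulted <- setdiff(.CONFIG_KEYS, names(cfg))
  if (!quiet && length(defaulted))
    message("using defaults for: ", paste(defaulted, collapse = ", "))
  thickness_um <- if ("film_thickness_um" %in% names(cfg))
    cfg$film_thickness_um else 55
  if (!is.numeric(thickness_um) || thickness_um <= 0)
    stop("'film_thickness_um' must be positive", call. = FALSE)
  n_nodes <- if ("n_nodes" %in% names(cfg)) cfg$n_nodes else 51L
  pargs <- cfg[intersect(names(cfg), setdiff(.CONFIG_KEYS,
                                             c("film_thickness_um",
                                               "n_nodes")))]
  params <- do.call(model_params, pargs)
  grid <- grid_spec(half_thickness = thickness_um * 1e-4 / 2,
                    n_nodes = n_nodes)
  list(params = params, grid = grid)
}
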