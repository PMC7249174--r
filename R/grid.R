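#' Construct a solubility grid
#'
#' A solubility grid is the central data container of the package: a tidy
#' table of saturation mole-fraction solubilities measured on a
#' (co-solvent mass fraction) x (absolute temperature) design, together
#' with metadata identifying the solute, the two solvents, the pressure and
#' any provenance notes (for example, corrections applied to a published
#' table). It is an ordinary tibble with extra attributes, so all the usual
#' data-manipulation verbs apply.
#'
#' Validation enforces the physical domain of every column: mass fractions
#' in \[0, 1\], temperatures strictly positive, mole fractions strictly
#' inside (0, 1) (values at or beyond the boundary would corrupt the log
#' transforms used by every downstream model and are rejected, not
#' clamped), standard deviations nonnegative when present, and uniqueness
#' of the (composition, temperature) design points.
#'
#' @param data A data frame with columns `mass_fraction_cosolvent`,
#'   `temperature_K`, `x_exp` and optionally `sd` (NA where unknown).
#' @param solute,cosolvent,antisolvent Character labels for the chemical
#'   species.
#' @param pressure_MPa Pressure of the measurements in MPa (`NA` if
#'   unspecified).
#' @param provenance Character vector of free-text provenance notes.
#' @return A `solubility_grid`: a tibble with the four data columns and
#'   `solute`, `cosolvent`, `antisolvent`, `pressure_MPa`, `provenance`
#'   attributes.
#' @seealso [read_grid()], [write_grid()], [reference_grid()],
#'   [generate_grid()]
#' @export
#' @examples
#' solubility_grid(
#'   data.frame(mass_fraction_cosolvent = c(0, 0, 1, 1),
#'              temperature_K = c(298.2, 308.2, 298.2, 308.2),
#'              x_exp = c(2e-5, 5e-5, 3e-2, 7e-2)),
#'   solute = "drug", cosolvent = "DMSO", antisolvent = "water")
solubility_grid <- function(data, solute = "", cosolvent = "",
                            antisolvent = "", pressure_MPa = NA_real_,
                            provenance = character()) {
  stopifnot(is.data.frame(data))
  required <- c("mass_fraction_cosolvent", "temperature_K", "x_exp")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"sd" %in% names(data)) data$sd <- NA_real_
  grid <- tibble::as_tibble(data[, c(required, "sd")])
  grid[required] <- lapply(grid[required], as.numeric)
  grid$sd <- as.numeric(grid$sd)
  attr(grid, "solute") <- as.character(solute)
  attr(grid, "cosolvent") <- as.character(cosolvent)
  attr(grid, "antisolvent") <- as.character(antisolvent)
  attr(grid, "pressure_MPa") <- as.numeric(pressure_MPa)
  attr(grid, "provenance") <- as.character(provenance)
  class(grid) <- c("solubility_grid", class(grid))
  validate_grid(grid)
  grid
}

# Row-numbered domain checks shared by the constructor and read_grid().
validate_grid <- function(grid) {
  bad_row <- function(cond, what) {
    if (any(cond, na.rm = TRUE)) {
      rows <- which(cond)
      stop(what, " in row(s) ", paste(rows, collapse = ", "), call. = FALSE)
    }
  }
  m <- grid$mass_fraction_cosolvent
  bad_row(is.na(m) | m < 0 | m > 1,
          "mass_fraction_cosolvent outside [0, 1]")
  bad_row(is.na(grid$temperature_K) | grid$temperature_K <= 0,
          "nonpositive temperature_K")
  bad_row(is.na(grid$x_exp) | grid$x_exp <= 0 | grid$x_exp >= 1,
          "x_exp outside the open interval (0, 1)")
  bad_row(!is.na(grid$sd) & grid$sd < 0, "negative sd")
  key <- paste(format(m, digits = 15), format(grid$temperature_K, digits = 15))
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))
    stop("duplicate (mass_fraction_cosolvent, temperature_K) pair in row(s) ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  invisible(grid)
}

#' @export
print.solubility_grid <- function(x, ...) {
  n_m <- length(unique(x$mass_fraction_cosolvent))
  n_t <- length(unique(x$temperature_K))
  cat(sprintf("<solubility_grid> %s in %s + %s: %d samples (%d compositions x %d temperatures)\n",
              attr(x, "solute"), attr(x, "cosolvent"), attr(x, "antisolvent"),
              nrow(x), n_m, n_t))
  if (!is.na(attr(x, "pressure_MPa"))) {
    cat(sprintf("  pressure: %g MPa\n", attr(x, "pressure_MPa")))
  }
  for (note in attr(x, "provenance")) cat("  note:", note, "\n")
  NextMethod()
}

#' Mole-fraction solubility from weighed masses
#'
#' Converts the weighed masses of solute, co-solvent and anti-solvent in a
#' saturated solution into the mole-fraction solubility of the solute,
#' x = n1 / (n1 + n2 + n3) with ni = mass_i / M_i. With no anti-solvent the
#' expression reduces to the binary solute + solvent form.
#'
#' @param mass_solute,mass_cosolvent,mass_antisolvent Masses in grams
#'   (vectors recycle as usual). `mass_antisolvent` defaults to 0.
#' @param molar_masses Named list with elements `solute`, `cosolvent`,
#'   `antisolvent` in g/mol; defaults to the baricitinib / DMSO / water
#'   values of [bnb_molar_masses()].
#' @return Mole fraction(s) of solute in \[0, 1).
#' @export
#' @examples
#' mole_fraction(0.1, 1.0)               # 0.1 g drug in 1 g DMSO
#' mole_fraction(371.41, 78.13)          # one mole of each -> 0.5
mole_fraction <- function(mass_solute, mass_cosolvent, mass_antisolvent = 0,
                          molar_masses = bnb_molar_masses()) {
  mm <- molar_masses
  if (any(c(mm$solute, mm$cosolvent, mm$antisolvent) <= 0)) {
    stop("molar masses must all be positive", call. = FALSE)
  }
  n <- max(length(mass_solute), length(mass_cosolvent), length(mass_antisolvent))
  m1 <- rep_len(mass_solute, n)
  m2 <- rep_len(mass_cosolvent, n)
  m3 <- rep_len(mass_antisolvent, n)
  if (any(m1 < 0 | m2 < 0 | m3 < 0)) {
    stop("masses must be nonnegative", call. = FALSE)
  }
  if (any(m1 + m2 + m3 == 0)) {
    stop("all masses are zero: no mixture", call. = FALSE)
  }
  n1 <- m1 / mm$solute
  n2 <- m2 / mm$cosolvent
  n3 <- m3 / mm$antisolvent
  n1 / (n1 + n2 + n3)
}

#' Read and write solubility grids as CSV
#'
#' The on-disk format is a plain comma-separated file (dot decimal, UTF-8,
#' scientific notation accepted) with columns `mass_fraction_cosolvent`,
#' `temperature_K`, `x_exp`, `sd` (the `sd` column may be empty), preceded
#' by `#`-prefixed key-value header lines carrying the grid metadata
#' (`solute`, `cosolvent`, `antisolvent`, `pressure_MPa` and one
#' `provenance` line per note). `read_grid(write_grid(g, path))` reproduces
#' `g` exactly.
#'
#' @param path Path to a CSV file.
#' @param grid A [solubility_grid()].
#' @return `read_grid` returns a validated `solubility_grid`; `write_grid`
#'   returns `path` invisibly.
#' @export
read_grid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  header <- grep("^#", lines, value = TRUE)
  meta <- list(solute = "", cosolvent = "", antisolvent = "",
               pressure_MPa = NA_real_, provenance = character())
  for (h in header) {
    kv <- sub("^#\\s*", "", h)
    key <- trimws(sub(":.*$", "", kv))
    val <- trimws(sub("^[^:]*:", "", kv))
    if (key == "provenance") {
      meta$provenance <- c(meta$provenance, val)
    } else if (key == "pressure_MPa") {
      meta$pressure_MPa <- if (val %in% c("", "NA")) NA_real_ else
        as.numeric(val)
    } else if (key %in% c("solute", "cosolvent", "antisolvent")) {
      meta[[key]] <- val
    }
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0) stop("no header row in ", path, call. = FALSE)
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE)
  solubility_grid(df, solute = meta$solute, cosolvent = meta$cosolvent,
                  antisolvent = meta$antisolvent,
                  pressure_MPa = meta$pressure_MPa,
                  provenance = meta$provenance)
}

#' @rdname read_grid
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "solubility_grid"))
  validate_grid(grid)
  con <- try(file(path, open = "wt", encoding = "UTF-8"), silent = TRUE)
  if (inherits(con, "try-error")) {
    stop("cannot open for writing: ", path, call. = FALSE)
  }
  on.exit(close(con))
  writeLines(c(
    paste0("# solute: ", attr(grid, "solute")),
    paste0("# cosolvent: ", attr(grid, "cosolvent")),
    paste0("# antisolvent: ", attr(grid, "antisolvent")),
    paste0("# pressure_MPa: ", format(attr(grid, "pressure_MPa"), digits = 15)),
    vapply(attr(grid, "provenance"), function(p) paste0("# provenance: ", p), "")
  ), con)
  df <- as.data.frame(grid)[, c("mass_fraction_cosolvent", "temperature_K",
                                "x_exp", "sd")]
  fmt <- function(v) ifelse(is.na(v), "", format(v, digits = 15))
  writeLines("mass_fraction_cosolvent,temperature_K,x_exp,sd", con)
  writeLines(paste(fmt(df$mass_fraction_cosolvent), fmt(df$temperature_K),
                   fmt(df$x_exp), fmt(df$sd), sep = ","), con)
  invisible(path)
}

#' The bundled baricitinib (DMSO + water) reference dataset
#'
#' Loads the published 11-composition x 5-temperature mole-fraction
#' solubility surface of baricitinib in DMSO + water mixtures at 0.1 MPa
#' (co-solvent mass fractions 0 to 1 in steps of 0.1; temperatures 298.2,
#' 303.2, 308.2, 313.2 and 323.2 K), with the printed standard deviations.
#'
#' One cell of the published table, (m = 0.2, T = 323.2 K) printed as
#' 7.05 x 10^-5, breaks the otherwise universal monotone increase of
#' solubility with temperature and contradicts the published van't Hoff
#' fit of its own series (a = 16.31, b = -7610.3 predicts about 7.2 x
#' 10^-4 there); it is treated as a power-of-ten typographical slip and
#' corrected to 7.05 x 10^-4 by default. The correction is recorded
#' machine-readably in the grid's `provenance` attribute, and
#' `corrected = FALSE` returns the verbatim table.
#'
#' @param corrected Apply the power-of-ten correction (default `TRUE`).
#' @return A [solubility_grid()] of 55 samples.
#' @export
#' @examples
#' g <- reference_grid()
#' subset(g, mass_fraction_cosolvent == 1)
reference_grid <- function(corrected = TRUE) {
  path <- system.file("extdata", "baricitinib_dmso_water.csv",
                      package = "cosolvr", mustWork = TRUE)
  grid <- read_grid(path)
  if (corrected) {
    idx <- which(grid$mass_fraction_cosolvent == 0.2 &
                 grid$temperature_K == 323.2)
    grid$x_exp[idx] <- 7.05e-4
    grid$sd[idx] <- 0.05e-4
    attr(grid, "provenance") <- c(
      attr(grid, "provenance"),
      "corrected cell (m=0.2, T=323.2 K): printed 7.05e-5 read as power-of-ten typo for 7.05e-4"
    )
  }
  grid
}

# (temperature, x) series of one composition, temperature-sorted.
grid_series <- function(grid, m) {
  sel <- grid$mass_fraction_cosolvent == m
  if (!any(sel)) {
    stop("no samples at mass_fraction_cosolvent = ", m, call. = FALSE)
  }
  s <- grid[sel, c("temperature_K", "x_exp")]
  s[order(s$temperature_K), ]
}

# Distinct compositions in ascending order.
grid_compositions <- function(grid) {
  sort(unique(grid$mass_fraction_cosolvent))
}
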