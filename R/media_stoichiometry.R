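#' Molecule count from a mass concentration
#'
#' Converts a formulation entry given as a mass concentration into an
#' absolute number of molecules: `conc * volume / molar_mass * N_A`, with
#' Avogadro's number N_A = 6.02214e23 /mol.
#'
#' @param conc Concentration in g/L (>= 0).
#' @param volume Volume in litres (> 0; default 1).
#' @param molar_mass Molar mass in g/mol (> 0).
#' @return Number of molecules (numeric, possibly very large).
#' @export
#' @examples
#' molecules_from_concentration(0.584, 1, 146.14) / 1e20  # glutamine in DMEM
molecules_from_concentration <- function(conc, volume = 1, molar_mass) {
  if (any(conc < 0)) stop("concentration must be non-negative")
  if (any(volume <= 0)) stop("volume must be positive")
  if (any(molar_mass <= 0)) stop("molar mass must be positive")
  conc * volume / molar_mass * 6.02214e23
}

#' Read a media formulation CSV
#'
#' Accepts either a `molecules` column (absolute counts), a
#' `molecules_1e20` column (counts in units of 1e20, the reporting
#' convention), or a `conc_g_per_L` column converted via
#' [molecules_from_concentration()] using the table's molar masses.
#' Amino acids absent from the file are read as zero supply.
#'
#' @param path CSV with column `amino_acid` plus one of the supply columns.
#' @param volume Litres of medium the counts refer to (used only for the
#'   concentration route).
#' @param table An [aa_table()].
#' @return Named numeric vector of molecule counts over the full alphabet.
#' @export
read_media_csv <- function(path, volume = 1, table = aa_table()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot("amino_acid" %in% names(df))
  aa <- toupper(trimws(df$amino_acid))
  if ("molecules" %in% names(df)) {
    mol <- df$molecules
  } else if ("molecules_1e20" %in% names(df)) {
    mol <- df$molecules_1e20 * 1e20
  } else if ("conc_g_per_L" %in% names(df)) {
    mol <- molecules_from_concentration(df$conc_g_per_L, volume,
                                        table$molar_mass[aa])
  } else {
    stop("media CSV needs one of: molecules, molecules_1e20, conc_g_per_L")
  }
  supply <- stats::setNames(numeric(20), table$alphabet)
  supply[aa] <- mol
  supply
}

#' Read a per-protein amino-acid demand CSV
#'
#' @param path CSV with columns `amino_acid`, `count` (residues per protein
#'   copy).
#' @param table An [aa_table()].
#' @return Named numeric vector over the full alphabet (missing entries 0).
#' @export
read_demand_csv <- function(path, table = aa_table()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("amino_acid", "count") %in% names(df)))
  demand <- stats::setNames(numeric(20), table$alphabet)
  demand[toupper(trimws(df$amino_acid))] <- df$count
  demand
}

#' Missing biosynthetic precursors in a medium
#'
#' Flags every non-essential amino acid that the medium does not supply and
#' whose biosynthetic precursor is also unsupplied — such products cannot be
#' obtained either directly or by conversion, making them potential limiting
#' factors beyond the formulation itself.
#'
#' @param supply Named molecule counts (any scale) over the alphabet.
#' @param table An [aa_table()]; its `precursors` map defines the pairing.
#' @return Data frame with columns `product`, `precursor`; zero rows when
#'   the medium is complete in this sense.
#' @export
precursor_gaps <- function(supply, table = aa_table()) {
  flags <- list()
  for (pre in names(table$precursors)) {
    if (isTRUE(supply[pre] > 0)) next
    for (prod in table$precursors[[pre]]) {
      if (!isTRUE(supply[prod] > 0)) {
        flags[[length(flags) + 1]] <- data.frame(product = prod,
                                                 precursor = pre,
                                                 stringsAsFactors = FALSE)
      }
    }
  }
  if (length(flags) == 0) {
    return(data.frame(product = character(), precursor = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, flags)
  out[order(out$product), , drop = FALSE]
}

#' Media capacity report
#'
#' Pure supply/demand stoichiometry: for each amino acid, the number of
#' protein copies its supply alone supports (`supply / demand`, `Inf` when
#' the protein does not use it), the limiting amino acid among the
#' essential set and among all demanded amino acids, the demanded amino
#' acids with zero supply, and the precursor gaps of the medium. Capacities
#' are real-valued ratios; rounding to the 2-decimal x1e18 reporting
#' convention is display-only (see [capacity_table()]).
#'
#' @param supply Named molecule counts over the alphabet (missing entries
#'   treated as 0).
#' @param demand Named residues-per-copy counts over the alphabet; at least
#'   one entry must be positive.
#' @param table An [aa_table()].
#' @return An object of class `capacity_report`: list with `max_copies`
#'   (named numeric), `limiting_eaa` and `limiting_overall` (each a list
#'   `amino_acid`/`max_copies`), `zero_supply` (character), and
#'   `precursor_gaps` (data frame).
#' @export
#' @examples
#' med <- media_fixture()
#' rep <- capacity(med$supply, med$demand)
#' rep$limiting_eaa
capacity <- function(supply, demand, table = aa_table()) {
  full_supply <- stats::setNames(numeric(20), table$alphabet)
  full_supply[names(supply)] <- supply
  full_demand <- stats::setNames(numeric(20), table$alphabet)
  full_demand[names(demand)] <- demand
  if (any(full_supply < 0) || any(full_demand < 0)) {
    stop("supply and demand must be non-negative")
  }
  if (all(full_demand == 0)) stop("demand is all-zero")

  max_copies <- ifelse(full_demand > 0, full_supply / full_demand, Inf)
  names(max_copies) <- table$alphabet

  demanded <- table$alphabet[full_demand > 0]
  argmin <- function(scope) {
    scope <- intersect(scope, demanded)
    if (length(scope) == 0) return(NULL)
    a <- scope[which.min(max_copies[scope])]
    list(amino_acid = a, max_copies = unname(max_copies[a]))
  }

  structure(
    list(
      max_copies       = max_copies,
      limiting_eaa     = argmin(table$essential),
      limiting_overall = argmin(table$alphabet),
      zero_supply      = demanded[full_supply[demanded] == 0],
      precursor_gaps   = precursor_gaps(full_supply, table),
      supply           = full_supply,
      demand           = full_demand
    ),
    class = "capacity_report"
  )
}

#' @export
print.capacity_report <- function(x, ...) {
  cat("Media capacity report\n")
  cat(sprintf("  limiting EAA:     %s (%.2f x 1e18 copies)\n",
              x$limiting_eaa$amino_acid, x$limiting_eaa$max_copies / 1e18))
  cat(sprintf("  limiting overall: %s (%.2f x 1e18 copies)\n",
              x$limiting_overall$amino_acid, x$limiting_overall$max_copies / 1e18))
  cat("  zero-supply amino acids:", paste(x$zero_supply, collapse = ", "), "\n")
  if (nrow(x$precursor_gaps) > 0) {
    cat("  precursor gaps:",
        paste(sprintf("%s (from %s)", x$precursor_gaps$product,
                      x$precursor_gaps$precursor), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Capacity report as a display table
#'
#' Per-amino-acid table in the reporting convention: supply in units of
#' 1e20 molecules and maximum copies in units of 1e18, both rounded half-up
#' to 2 decimals.
#'
#' @param report A [capacity()] result.
#' @return Data frame with columns `amino_acid`, `demand`, `supply_1e20`,
#'   `max_copies_1e18`.
#' @export
capacity_table <- function(report) {
  stopifnot(inherits(report, "capacity_report"))
  data.frame(
    amino_acid      = names(report$max_copies),
    demand          = unname(report$demand),
    supply_1e20     = round_half_up(unname(report$supply) / 1e20, 2),
    max_copies_1e18 = ifelse(is.infinite(report$max_copies), Inf,
                             round_half_up(unname(report$max_copies) / 1e18, 2)),
    stringsAsFactors = FALSE
  )
}

#' Write a capacity report as JSON
#'
#' Stable key order, raw (unrounded) capacities plus the display table.
#'
#' @param report A [capacity()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_capacity_json <- function(report, path) {
  stopifnot(inherits(report, "capacity_report"))
  obj <- list(
    limiting_eaa     = report$limiting_eaa,
    limiting_overall = report$limiting_overall,
    zero_supply      = report$zero_supply,
    precursor_gaps   = report$precursor_gaps,
    max_copies       = as.list(report$max_copies),
    table            = capacity_table(report)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
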