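#' Host-range infection matrix
#'
#' A boolean host x phage matrix of which phage can infect which bacteria.
#' Rows are hosts, columns phage.
#'
#' @param mask Logical (or 0/1) matrix, hosts as rows, phage as columns.
#' @param hosts,phages Identifier vectors; default taken from dimnames.
#' @return An object of class `infection_matrix`.
#' @export
infection_matrix <- function(mask, hosts = rownames(mask),
                             phages = colnames(mask)) {
  mask <- as.matrix(mask)
  if (!all(mask %in% c(0, 1, TRUE, FALSE))) {
    stop("infection matrix entries must be 0/1", call. = FALSE)
  }
  mode(mask) <- "logical"
  if (is.null(hosts)) hosts <- paste0("host", seq_len(nrow(mask)))
  if (is.null(phages)) phages <- paste0("phage", seq_len(ncol(mask)))
  stopifnot(length(hosts) == nrow(mask), length(phages) == ncol(mask))
  dimnames(mask) <- list(hosts, phages)
  structure(list(hosts = as.character(hosts), phages = as.character(phages),
                 mask = mask),
            class = "infection_matrix")
}

#' @export
print.infection_matrix <- function(x, ...) {
  cat(sprintf("<infection_matrix> %d hosts x %d phages, %d interactions\n",
              length(x$hosts), length(x$phages), sum(x$mask)))
  print(1 * x$mask)
  invisible(x)
}

#' Interacting pairs of an infection matrix
#'
#' @param x An `infection_matrix`.
#' @return A tibble with columns `host_id`, `phage_id`, one row per
#'   interacting (TRUE) entry, in column-major order.
#' @export
interacting_pairs <- function(x) {
  stopifnot(inherits(x, "infection_matrix"))
  idx <- which(x$mask, arr.ind = TRUE)
  idx <- idx[order(idx[, "col"], idx[, "row"]), , drop = FALSE]
  tibble::tibble(host_id = x$hosts[idx[, "row"]],
                 phage_id = x$phages[idx[, "col"]])
}

#' Default five-host / five-phage infection network
#'
#' The modular host-range network used throughout the package examples:
#' five marine bacterial strains (three *Cellulophaga baltica*, two
#' *Pseudoalteromonas*) and five associated virulent phage, with nine
#' realised infections out of twenty-five possible and no cross-infection
#' between the CBA and PSA modules. This is the packaged default; any
#' host-range matrix can be supplied instead (see [read_infection_matrix()]).
#'
#' @return An `infection_matrix` with 9 of 25 entries TRUE.
#' @export
default_infection_matrix <- function() {
  hosts <- c("CBA38", "CBA4", "CBA18", "PSAH100", "PSA1315")
  phages <- c("phi38:1", "phi18:2", "phi18:3", "PSA-HP1", "PSA-HS6")
  mask <- matrix(FALSE, 5, 5, dimnames = list(hosts, phages))
  mask["CBA38", "phi38:1"] <- TRUE
  mask["CBA18", "phi38:1"] <- TRUE
  mask["CBA18", "phi18:2"] <- TRUE
  mask["CBA4", "phi18:3"] <- TRUE
  mask["CBA18", "phi18:3"] <- TRUE
  mask["PSAH100", "PSA-HP1"] <- TRUE
  mask["PSA1315", "PSA-HP1"] <- TRUE
  mask["PSAH100", "PSA-HS6"] <- TRUE
  mask["PSA1315", "PSA-HS6"] <- TRUE
  infection_matrix(mask)
}

#' Synthetic default per-pair trait table
#'
#' Ground-truth life-history traits for the nine interacting pairs of
#' [default_infection_matrix()], chosen inside the experimentally observed
#' ranges for this system: host doubling times 4.2-5.8 h (CBA) and
#' 3.6-3.8 h (PSA), adsorption rates 2e-8 to 2e-7 ml/h, mean latent periods
#' 0.5-1.5 h with latent-period CV 0.1 (99 exposed stages), and burst sizes
#' of order tens of virions per cell. These values are synthetic stand-ins
#' for recovery benchmarks, not measured estimates.
#'
#' @return A trait table tibble (see [trait_table()]).
#' @export
default_trait_table <- function() {
  pairs <- interacting_pairs(default_infection_matrix())
  doubling <- c(CBA38 = 4.2, CBA4 = 5.0, CBA18 = 5.8,
                PSAH100 = 3.6, PSA1315 = 3.8)
  phi <- c(2e-8, 5e-8, 1e-7, 4e-8, 8e-8, 2e-7, 1e-7, 6e-8, 1.5e-7)
  tau <- c(1.2, 1.5, 1.0, 0.9, 1.1, 0.8, 1.0, 1.3, 0.7)
  beta <- c(30, 20, 50, 45, 60, 80, 50, 25, 40)
  trait_table(pairs$host_id, pairs$phage_id,
              r = log(2) / doubling[pairs$host_id],
              phi = phi, tau = tau, n_e = 99L, beta = beta)
}
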