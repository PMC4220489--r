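# Synthetic fixture generation: clone panels with defined deletion
# classes, and noisy assay datasets with known truth parameters. All
# fixtures are deterministic for a fixed seed.

#' Generate a synthetic clone panel with defined deletion classes
#'
#' Samples clones from a library design and then applies the observed
#' deletion architectures: `del_two_heptads` removes the two internal
#' heptads of helix B, `del_helix_B` removes linker 1 plus the entire
#' helix B, `only_helix_C` keeps only linker 2 plus helix C. The returned
#' panel carries its ground-truth class, so a QC summary can be checked
#' against the requested composition (e.g. 35 intact + 35 del_helix_B +
#' 5 del_two_heptads + 5 only_helix_C reproduces the 56% defective
#' fraction seen in the sequenced binder panel).
#'
#' @param composition Named integer vector of per-class counts; names from
#'   `intact`, `del_two_heptads`, `del_helix_B`, `only_helix_C`.
#' @param design `ab_library` the clones are sampled from.
#' @param seed Integer seed; fixes the panel exactly.
#' @return Tibble `id`, `aa_sequence`, `source_library`, `class_truth`,
#'   plus the sampled residues per randomized position.
#' @export
generate_clone_panel <- function(composition, design = make_named_library("scLib_AC11"),
                                 seed = 1L) {
  stopifnot(all(composition >= 0),
            all(names(composition) %in% ARCH_CLASSES))
  n <- sum(composition)
  clones <- sample_clones(design, n, seed = seed)
  reg <- scaffold_registry(design$base)
  idx_of <- function(seg) reg$residue_index[reg$segment == seg]
  classes <- rep(names(composition), composition)
  clones$class_truth <- classes
  clones$aa_sequence <- vapply(seq_len(n), function(i) {
    aa <- strsplit(clones$aa_sequence[i], "")[[1]]
    keep <- switch(
      classes[i],
      intact = seq_along(aa),
      # drop the two internal heptads (IAAIQKQ x2) of helix B
      del_two_heptads = setdiff(seq_along(aa), idx_of("B")[8:21]),
      # drop linker 1 and the whole helix B
      del_helix_B = setdiff(seq_along(aa), c(idx_of("L1"), idx_of("B"))),
      # keep only linker 2 and helix C
      only_helix_C = c(idx_of("L2"), idx_of("C"))
    )
    paste(aa[keep], collapse = "")
  }, character(1))
  clones
}

#' Write a synthetic assay fixture with known truth parameters
#'
#' Wraps the binding-model simulators and writes the dataset in the CSV
#' schema the matching loader/fitter expects, together with a sidecar
#' `<stem>_truth.csv` recording the generating parameters.
#'
#' @param kind One of `"kinelisa"`, `"inhibition"`, `"spr"`, `"itc"`,
#'   `"melt"`.
#' @param truth Named list of generating parameters for that kind (see
#'   the corresponding simulator); missing entries use the defaults of the
#'   high-affinity reference interaction.
#' @param noise_sd Gaussian noise SD in the response unit.
#' @param seed Integer seed.
#' @param dir Output directory.
#' @param stem File stem (defaults to the kind).
#' @return Named character vector of the files written (`data`, `truth`,
#'   and `calibration` for the inhibition kind), invisibly a list with the
#'   simulated tibbles under `$tables`.
#' @export
generate_assay_fixture <- function(kind = c("kinelisa", "inhibition", "spr",
                                            "itc", "melt"),
                                   truth = list(), noise_sd = 0, seed = 1L,
                                   dir = tempdir(), stem = NULL) {
  kind <- match.arg(kind)
  stem <- stem %||% kind
  data_path <- file.path(dir, paste0(stem, ".csv"))
  truth_path <- file.path(dir, paste0(stem, "_truth.csv"))
  files <- c(data = data_path, truth = truth_path)
  tables <- list()
  if (kind == "kinelisa") {
    tr <- utils::modifyList(list(
      K_D = 7e-9, k_on = 1e5, od_max = 1,
      concs = 1e-6 / 5^(0:7),
      times = c(24 * 3600, 3 * 3600, 3600, 15 * 60, 8 * 60, 4 * 60)
    ), truth)
    params <- kinetic_params(tr$k_on, koff_from_kd(tr$K_D, tr$k_on))
    tab <- simulate_kinetic_elisa(params, tr$concs, tr$times, tr$od_max,
                                  noise_sd, seed)
    utils::write.csv(tab, data_path, row.names = FALSE)
    tables$data <- tab
  } else if (kind == "inhibition") {
    tr <- utils::modifyList(list(
      K_I = 0.13e-9, L_tot = 2.6e-12,
      inhibitor_M = c(0, 1e-6 / 5^(0:9)),
      cal_M = 10e-9 / 5^(0:7), cal_top = 2, cal_ec50 = 2.6e-12, cal_h = 1
    ), truth)
    cal <- tibble(
      target_M = tr$cal_M,
      response = tr$cal_top * tr$cal_M / (tr$cal_M + tr$cal_ec50)
    )
    lf <- free_ligand_with_inhibitor(tr$L_tot, tr$inhibitor_M, tr$K_I)
    inh <- tibble(
      inhibitor_M = tr$inhibitor_M,
      response = tr$cal_top * lf / (lf + tr$cal_ec50)
    )
    if (noise_sd > 0) {
      set.seed(seed)
      cal$response <- cal$response + stats::rnorm(nrow(cal), 0, noise_sd)
      inh$response <- inh$response + stats::rnorm(nrow(inh), 0, noise_sd)
    }
    cal_path <- file.path(dir, paste0(stem, "_calibration.csv"))
    utils::write.csv(inh, data_path, row.names = FALSE)
    utils::write.csv(cal, cal_path, row.names = FALSE)
    files <- c(files, calibration = cal_path)
    tables$data <- inh
    tables$calibration <- cal
  } else if (kind == "spr") {
    tr <- utils::modifyList(list(
      k_on = 2.6e5, k_off = 1.2e-4, Rmax = 43,
      concs = c(0.5, 2, 8, 20, 40) * 1e-9,
      t_assoc = 180, t_dissoc = 1200, dt = 2
    ), truth)
    params <- kinetic_params(tr$k_on, tr$k_off)
    tab <- bind_rows(lapply(seq_along(tr$concs), function(i) {
      simulate_sensorgram(params, tr$concs[i], tr$Rmax, tr$t_assoc,
                          tr$t_dissoc, tr$dt, noise_sd,
                          seed = if (is.null(seed)) NULL else seed + i)
    }))
    utils::write.csv(tab, data_path, row.names = FALSE)
    tables$data <- tab
  } else if (kind == "itc") {
    tr <- utils::modifyList(list(
      N = 1, K_D = 0.35e-9, dH = -8e4,
      cell_M = 4.9e-6, syringe_M = 53.2e-6,
      injection_volumes_L = c(3e-6, rep(5e-6, 29)),
      cell_volume_L = 1.4e-3, temperature_K = 303.15
    ), truth)
    tab <- itc_one_site_heats(tr$N, tr$K_D, tr$dH, tr$cell_M, tr$syringe_M,
                              tr$injection_volumes_L, tr$cell_volume_L,
                              tr$temperature_K, noise_sd, seed)
    utils::write.csv(tab, data_path, row.names = FALSE)
    tables$data <- tab
  } else { # melt
    tr <- utils::modifyList(list(
      Tm = 70, width = 2.5, yf = -20, yu = -2,
      temperature = seq(30, 110, by = 1), guhcl_M = 4
    ), truth)
    k <- exp((tr$temperature - tr$Tm) / tr$width)
    sig <- (tr$yf + tr$yu * k) / (1 + k)
    if (noise_sd > 0) {
      set.seed(seed)
      sig <- sig + stats::rnorm(length(sig), 0, noise_sd)
    }
    tab <- tibble(temp_C = tr$temperature, signal = sig, guhcl_M = tr$guhcl_M)
    utils::write.csv(tab, data_path, row.names = FALSE)
    tables$data <- tab
  }
  truth_flat <- truth_as_row(if (exists("tr")) tr else truth)
  utils::write.csv(truth_flat, truth_path, row.names = FALSE)
  out <- files
  attr(out, "tables") <- tables
  invisible(out)
}

truth_as_row <- function(tr) {
  scalars <- tr[vapply(tr, function(v) is.numeric(v) && length(v) == 1L,
                       logical(1))]
  as_tibble(scalars)
}
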