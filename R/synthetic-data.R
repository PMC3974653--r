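#' Tested concentration series of the screen
#'
#' The screening library is prepared as interplate titrations serially
#' diluted 1:2.236 in DMSO; cells are exposed to 8 selected concentrations
#' from that series. Consecutive *tested* points are alternate members of
#' the 1:2.236 series, so they differ by a factor of 2.236^2 = 5.000 and the
#' 8 points span 0.589 nM - 46 uM (the familiar "0.5 nM to 46 uM" range).
#'
#' @param c_max highest tested concentration, uM.
#' @param n_conc number of titration points.
#' @param dilution fold-dilution between consecutive tested points.
#' @return strictly increasing numeric vector of concentrations in uM.
#' @export
qhts_concentrations <- function(c_max = 46, n_conc = 8, dilution = 2.236^2) {
  stopifnot(c_max > 0, n_conc >= 2, dilution > 1)
  sort(c_max / dilution^(seq_len(n_conc) - 1))
}

# Per-class planting windows. IC50 windows (uM) keep each class's curve
# shape unambiguous over the 8-point 0.589 nM - 46 uM series: complete
# curves (1.x) plateau at both ends with >=2 supporting points; incomplete
# curves (2.x) reach their upper asymptote at the top concentration only;
# class 3 shows response at the single highest concentration.
.class_windows <- list(
  "1.1" = list(ic50 = c(0.02, 2),  hill = c(1.8, 3),   eff = c(85, 100)),
  "1.2" = list(ic50 = c(0.02, 2),  hill = c(1.8, 3),   eff = c(62, 78)),
  "2.1" = list(ic50 = c(10, 22),   hill = c(1.5, 2.5), eff = c(85, 105)),
  "2.2" = list(ic50 = c(10, 22),   hill = c(1.5, 2.5), eff = c(62, 78)),
  "3"   = list(ic50 = c(60, 80),   hill = c(3, 5),     eff = c(35, 50)),
  "4"   = list(ic50 = c(NA, NA),   hill = c(NA, NA),   eff = c(0, 0))
)

.default_categories <- c(
  "antineoplastic", "antiseptic", "antimalarial", "estrogen", "anthelmintic",
  "antibiotic", "antihypertensive", "antidepressant", "antihistamine",
  "analgesic", "antidiabetic", "anti-inflammatory"
)

.fpl <- function(x, bottom, top, ic50, hill) {
  bottom + (top - bottom) / (1 + (ic50 / x)^hill)
}

#' Generate a synthetic screening library with planted curve classes
#'
#' Emulates a pharmaceutical-collection screen: each compound carries a true
#' concentration-response curve class, IC50, Hill slope and efficacy.
#' Efficacies are planted at least 2 percentage points away from the 60%/80%
#' triage boundaries so noiseless classification recovery is deterministic.
#' Class 4 compounds are flat (no fitted curve); class 3 compounds respond
#' only at the highest tested concentration.
#'
#' @param n_compounds number of compounds.
#' @param class_mix named numeric vector/list of class proportions over
#'   `c("1.1","1.2","2.1","2.2","3","4")`; must sum to 1 within 1e-9.
#' @param seed integer seed.
#' @param categories therapeutic-category labels sampled per compound.
#' @param concentrations tested concentration series (uM).
#' @return data.frame with columns compound_id, true_class, true_ic50,
#'   true_hill, true_top, true_bottom, true_efficacy (observed-window
#'   efficacy over the tested range), category.
#' @export
gen_screen_library <- function(n_compounds, class_mix, seed,
                               categories = .default_categories,
                               concentrations = qhts_concentrations()) {
  stopifnot(n_compounds >= 1)
  mix <- unlist(class_mix)
  if (is.null(names(mix)) || !all(names(mix) %in% names(.class_windows)))
    stop_input("class_mix must be named with curve classes among: ",
               paste(names(.class_windows), collapse = ", "))
  if (abs(sum(mix) - 1) > 1e-9)
    stop_input("class_mix proportions must sum to 1 (got ", sum(mix), ")")

  # largest-remainder apportionment so counts match proportions to rounding
  raw <- mix * n_compounds
  cnt <- floor(raw)
  rem <- n_compounds - sum(cnt)
  if (rem > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
  }
  classes <- rep(names(cnt), cnt)

  c_min <- min(concentrations); c_max <- max(concentrations)
  with_seed(seed, {
    n <- n_compounds
    ic50 <- hill <- top <- eff <- numeric(n)
    for (cl in unique(classes)) {
      idx <- which(classes == cl)
      w <- .class_windows[[cl]]
      if (cl == "4") {
        ic50[idx] <- NA_real_; hill[idx] <- NA_real_
        top[idx] <- 0; eff[idx] <- 0
      } else {
        ic50[idx] <- exp(stats::runif(length(idx), log(w$ic50[1]), log(w$ic50[2])))
        hill[idx] <- stats::runif(length(idx), w$hill[1], w$hill[2])
        eff[idx]  <- stats::runif(length(idx), w$eff[1], w$eff[2])
        # scale the asymptote so the *observed* window over the tested
        # range equals the planted efficacy
        frac <- 1 / (1 + (ic50[idx] / c_max)^hill[idx]) -
                1 / (1 + (ic50[idx] / c_min)^hill[idx])
        top[idx] <- eff[idx] / frac
      }
    }
    data.frame(
      compound_id = sprintf("CPD%05d", seq_len(n)),
      true_class = classes,
      true_ic50 = ic50,
      true_hill = hill,
      true_top = top,
      true_bottom = 0,
      true_efficacy = eff,
      category = sample(categories, n, replace = TRUE),
      stringsAsFactors = FALSE
    )
  })
}

#' Default 1536-well plate geometry
#'
#' 32 rows x 48 columns; columns 1-4 hold the controls (columns 1-2
#' DMSO-only basal wells, columns 3-4 positive-control wells at full
#' inhibition). Raw reads are luminescence-like counts anchored by the
#' control levels: DMSO wells read high (viable cells), positive-control
#' wells read low.
#'
#' @param n_rows,n_cols plate dimensions.
#' @param control_cols columns reserved for controls.
#' @param dmso_level,pos_level expected raw counts of the control wells.
#' @export
plate_layout <- function(n_rows = 32, n_cols = 48, control_cols = 1:4,
                         dmso_level = 2000, pos_level = 200) {
  stopifnot(n_rows >= 1, n_cols > length(control_cols))
  list(n_rows = n_rows, n_cols = n_cols, control_cols = control_cols,
       dmso_level = dmso_level, pos_level = pos_level)
}

#' Generate raw plate reads for a synthetic library
#'
#' Each compound occupies 8 sample wells (one per titration point). The
#' normalized inhibition implied by the planted four-parameter logistic
#' curve is perturbed with additive Gaussian noise on the normalized scale
#' (default 3% of the control-defined signal window) and mapped into
#' raw-count space anchored by the DMSO and positive-control levels.
#'
#' @param truth library table from [gen_screen_library()].
#' @param layout plate geometry from [plate_layout()].
#' @param noise_sd Gaussian noise sd in % of the signal window.
#' @param seed integer seed.
#' @param concentrations tested concentration series (uM).
#' @return list with `plates` (plate_id, row, col, read, role) and `map`
#'   (compound_id, plate_id, row, col, conc_index, concentration, category).
#' @export
gen_plate_reads <- function(truth, layout = plate_layout(), noise_sd = 3,
                            seed = 1, concentrations = qhts_concentrations()) {
  ctrl_cols <- layout$control_cols
  n_ctrl <- length(ctrl_cols) * layout$n_rows
  if (floor(n_ctrl / 2) < 2 || length(ctrl_cols) < 2)
    stop_input("layout must reserve at least 2 wells per control group")
  dmso_cols <- ctrl_cols[seq_len(ceiling(length(ctrl_cols) / 2))]
  pos_cols <- setdiff(ctrl_cols, dmso_cols)

  n_conc <- length(concentrations)
  sample_cols <- setdiff(seq_len(layout$n_cols), ctrl_cols)
  wells_per_plate <- layout$n_rows * length(sample_cols)
  cpds_per_plate <- wells_per_plate %/% n_conc
  if (cpds_per_plate < 1) stop_input("plate too small for one titration")
  n_plates <- ceiling(nrow(truth) / cpds_per_plate)

  window <- layout$pos_level - layout$dmso_level  # raw counts per 100%
  to_raw <- function(resp) layout$dmso_level + window * resp / 100

  with_seed(seed, {
    plates <- vector("list", n_plates)
    maps <- vector("list", n_plates)
    for (p in seq_len(n_plates)) {
      i0 <- (p - 1) * cpds_per_plate
      idx <- seq(i0 + 1, min(i0 + cpds_per_plate, nrow(truth)))
      tr <- truth[idx, , drop = FALSE]

      # control wells
      ctrl <- expand.grid(row = seq_len(layout$n_rows), col = ctrl_cols)
      ctrl$role <- ifelse(ctrl$col %in% dmso_cols, "dmso", "pos_ctrl")
      ctrl_resp <- ifelse(ctrl$role == "dmso", 0, 100) +
        stats::rnorm(nrow(ctrl), 0, noise_sd)

      # sample wells: compound-major, 8 consecutive wells per compound
      nwell <- nrow(tr) * n_conc
      grid <- expand.grid(row = seq_len(layout$n_rows), col = sample_cols)
      grid <- grid[order(grid$row, grid$col), ][seq_len(nwell), , drop = FALSE]
      conc <- rep(concentrations, times = nrow(tr))
      resp_true <- numeric(nwell)
      act <- rep(!is.na(tr$true_ic50), each = n_conc)
      if (any(act)) {
        j <- rep(seq_len(nrow(tr)), each = n_conc)[act]
        resp_true[act] <- .fpl(conc[act], tr$true_bottom[j], tr$true_top[j],
                               tr$true_ic50[j], tr$true_hill[j])
      }
      resp <- resp_true + stats::rnorm(nwell, 0, noise_sd)

      pid <- sprintf("plate%03d", p)
      plates[[p]] <- data.frame(
        plate_id = pid,
        row = c(ctrl$row, grid$row),
        col = c(ctrl$col, grid$col),
        read = c(to_raw(ctrl_resp), to_raw(resp)),
        role = c(ctrl$role, rep("sample", nwell)),
        stringsAsFactors = FALSE
      )
      maps[[p]] <- data.frame(
        compound_id = rep(tr$compound_id, each = n_conc),
        plate_id = pid,
        row = grid$row,
        col = grid$col,
        conc_index = rep(seq_len(n_conc), times = nrow(tr)),
        concentration = conc,
        category = rep(tr$category, each = n_conc),
        stringsAsFactors = FALSE
      )
    }
    list(plates = do.call(rbind, plates), map = do.call(rbind, maps))
  })
}

#' Generate a paired cross-species expression data set
#'
#' Emulates a murine cell-line microarray (triplicate samples, title-case
#' gene symbols) paired with a human tumor microarray (uppercase symbols).
#' Gene-level log2 means are drawn from a bivariate normal with correlation
#' `rho` across the two data sets; sample-level replicates add Gaussian
#' noise. A configurable fraction of genes is private to each data set, and
#' an optional divergent fraction receives a cross-data-set mean shift of at
#' least `divergent_shift[1]` log2 units (these are the genes a <2-fold
#' filter removes).
#'
#' @param n_genes number of *shared* genes.
#' @param n_samples_a,n_samples_b samples per data set.
#' @param rho target correlation of shared gene means, in `[-1, 1]`.
#' @param seed integer seed.
#' @param frac_private fraction of extra genes private to each data set.
#' @param frac_divergent fraction of shared genes given a large mean shift.
#' @param gene_sd sd of gene-level log2 means.
#' @param sample_sd sd of per-sample noise (0.08 gives replicate
#'   correlations ~0.98, matching high-quality array replicates).
#' @param base_mean grand mean on the log2 scale.
#' @param divergent_shift range of the absolute log2 shift for divergent genes.
#' @return list with `a`, `b` (expression matrices with `species`,
#'   `symbol` rownames and unset z-score state), `shared_genes` (uppercase
#'   namespace) and `divergent_genes`.
#' @export
gen_expression_pair <- function(n_genes, n_samples_a = 3, n_samples_b = 10,
                                rho = 0.86, seed = 1, frac_private = 0.1,
                                frac_divergent = 0, gene_sd = 0.6,
                                sample_sd = 0.08, base_mean = 8,
                                divergent_shift = c(1.5, 3)) {
  if (n_genes < 3) stop_input("n_genes must be >= 3 (correlation undefined)")
  if (rho < -1 || rho > 1) stop_input("rho must lie in [-1, 1]")
  stopifnot(n_samples_a >= 1, n_samples_b >= 1)

  with_seed(seed, {
    sym_up <- sprintf("GENE%05d", seq_len(n_genes))
    z1 <- stats::rnorm(n_genes); z2 <- stats::rnorm(n_genes)
    mu_a <- base_mean + gene_sd * z1
    mu_b <- base_mean + gene_sd * (rho * z1 + sqrt(1 - rho^2) * z2)

    n_div <- round(frac_divergent * n_genes)
    div <- integer(0)
    if (n_div > 0) {
      div <- sample.int(n_genes, n_div)
      shift <- stats::runif(n_div, divergent_shift[1], divergent_shift[2]) *
        sample(c(-1, 1), n_div, replace = TRUE)
      mu_b[div] <- mu_b[div] + shift
    }

    n_priv <- round(frac_private * n_genes)
    mu_pa <- base_mean + gene_sd * stats::rnorm(n_priv)
    mu_pb <- base_mean + gene_sd * stats::rnorm(n_priv)

    make <- function(mu, syms, n_samp, prefix) {
      m <- matrix(rep(mu, n_samp), ncol = n_samp) +
        stats::rnorm(length(mu) * n_samp, 0, sample_sd)
      rownames(m) <- syms
      colnames(m) <- sprintf("%s%02d", prefix, seq_len(n_samp))
      m
    }
    mouse_case <- function(s) paste0(substr(s, 1, 1),
                                     tolower(substr(s, 2, nchar(s))))
    a <- make(c(mu_a, mu_pa),
              mouse_case(c(sym_up, sprintf("MPRIV%04d", seq_len(n_priv)))),
              n_samples_a, "MTT_")
    b <- make(c(mu_b, mu_pb),
              c(sym_up, sprintf("HPRIV%04d", seq_len(n_priv))),
              n_samples_b, "SDHB_")
    list(a = expression_matrix(a, species = "mouse"),
         b = expression_matrix(b, species = "human"),
         shared_genes = sym_up,
         divergent_genes = sym_up[sort(div)])
  })
}

#' Generate a sparse drug-target bipartite map
#'
#' Defaults emulate the published compilation: 22 screened drugs mapped to
#' 2129 target genes through 3091 drug-gene pairs (some genes are targets
#' of more than one drug). Every gene gets at least one drug and every drug
#' at least one gene.
#'
#' @param n_drugs,n_genes,n_edges map dimensions; `n_edges >= max(n_genes,
#'   n_drugs)`.
#' @param seed integer seed.
#' @return data.frame with columns drug, gene (uppercase symbols).
#' @export
gen_drug_target_map <- function(n_drugs = 22, n_genes = 2129,
                                n_edges = 3091, seed = 1) {
  stopifnot(n_drugs >= 1, n_genes >= 1, n_edges >= n_genes, n_edges >= n_drugs)
  with_seed(seed, {
    drugs <- sprintf("drug%02d", seq_len(n_drugs))
    genes <- sprintf("GENE%05d", seq_len(n_genes))
    # each gene one drug (round-robin start covers every drug), then extra
    # pairs until the edge budget is reached
    base <- data.frame(
      drug = drugs[((seq_len(n_genes) - 1) %% n_drugs) + 1],
      gene = genes, stringsAsFactors = FALSE
    )
    need <- n_edges - n_genes
    extra <- data.frame(drug = character(0), gene = character(0))
    while (need > 0) {
      cand <- data.frame(drug = sample(drugs, 2 * need, replace = TRUE),
                         gene = sample(genes, 2 * need, replace = TRUE),
                         stringsAsFactors = FALSE)
      all_e <- rbind(base, extra, cand)
      keep <- !duplicated(paste(all_e$drug, all_e$gene, sep = "\r"))
      all_e <- all_e[keep, , drop = FALSE]
      extra <- all_e[-seq_len(nrow(base)), , drop = FALSE]
      extra <- extra[seq_len(min(nrow(extra), n_edges - n_genes)), , drop = FALSE]
      need <- n_edges - n_genes - nrow(extra)
    }
    out <- rbind(base, extra)
    rownames(out) <- NULL
    out
  })
}

#' Define the true parameters of a synthetic drug combination
#'
#' @param dm1,dm2 median-effect doses of the two drugs (same units as the
#'   doses you will generate).
#' @param m1,m2 sigmoidicity exponents (> 0 for inhibitors).
#' @param ratio constant dose ratio drug2:drug1.
#' @param ci_true target combination index planted at every dose level.
#' @param noise_sd Gaussian noise sd added to generated fraction-affected.
#' @export
combination_truth <- function(dm1, dm2, m1, m2, ratio, ci_true,
                              noise_sd = 0) {
  if (dm1 <= 0 || dm2 <= 0) stop_input("median-effect doses must be > 0")
  if (m1 <= 0 || m2 <= 0) stop_input("sigmoidicity exponents must be > 0")
  if (ratio <= 0) stop_input("dose ratio must be > 0")
  if (ci_true <= 0) stop_input("ci_true must be > 0")
  structure(list(dm1 = dm1, dm2 = dm2, m1 = m1, m2 = m2, ratio = ratio,
                 ci_true = ci_true, noise_sd = noise_sd),
            class = "combination_truth")
}

.me_fa <- function(d, dm, m) {
  r <- (d / dm)^m
  r / (1 + r)
}

#' Generate a constant-ratio combination assay with known combination index
#'
#' Produces the three tables a median-effect combination analysis consumes:
#' two single-drug dose/fraction-affected titrations (drawn exactly from the
#' planted median-effect curves) and a constant-ratio combination table
#' whose fraction-affected values solve, before noise, the Chou-Talalay
#' relation `d1/Dx1(fa) + d2/Dx2(fa) = ci_true` at every dose level.
#'
#' @param truth a [combination_truth()] object.
#' @param dose_levels fold-multipliers of the (dm1, dm1*ratio) anchor pair,
#'   or a data.frame with columns dose1, dose2 sharing the truth's ratio.
#' @param seed integer seed.
#' @param n_single number of single-drug titration points per drug.
#' @return list of data.frames `single1`, `single2` (dose, fa), `combo`
#'   (dose1, dose2, fa, clipped) plus the `truth` object.
#' @export
gen_combination_assay <- function(truth, dose_levels = c(4, 2, 1, 0.5, 0.25),
                                  seed = 1, n_single = 8) {
  stopifnot(inherits(truth, "combination_truth"))
  if (is.data.frame(dose_levels)) {
    pairs <- dose_levels
    stopifnot(all(c("dose1", "dose2") %in% names(pairs)))
    rat <- pairs$dose2 / pairs$dose1
    if (any(abs(rat / truth$ratio - 1) > 1e-6))
      stop_input("dose pairs must share the truth's constant ratio")
  } else {
    pairs <- data.frame(dose1 = dose_levels * truth$dm1,
                        dose2 = dose_levels * truth$dm1 * truth$ratio)
  }

  # fa solving the planted combination index at a ratio-preserving pair
  solve_fa <- function(d1, d2) {
    g <- function(lg) {  # lg = logit(fa)
      fa <- stats::plogis(lg)
      dx1 <- truth$dm1 * (fa / (1 - fa))^(1 / truth$m1)
      dx2 <- truth$dm2 * (fa / (1 - fa))^(1 / truth$m2)
      d1 / dx1 + d2 / dx2 - truth$ci_true
    }
    stats::plogis(stats::uniroot(g, c(-30, 30), tol = 1e-13)$root)
  }

  with_seed(seed, {
    fa0 <- vapply(seq_len(nrow(pairs)),
                  function(i) solve_fa(pairs$dose1[i], pairs$dose2[i]),
                  numeric(1))
    fa <- fa0 + stats::rnorm(length(fa0), 0, truth$noise_sd)
    clipped <- fa <= 0 | fa >= 1
    fa <- pmin(pmax(fa, 1e-6), 1 - 1e-6)
    combo <- data.frame(dose1 = pairs$dose1, dose2 = pairs$dose2,
                        fa = fa, clipped = clipped)

    single <- function(dm, m) {
      d <- dm * 2^seq(-(n_single - 1) / 2, (n_single - 1) / 2, length.out = n_single)
      f <- .me_fa(d, dm, m) + stats::rnorm(n_single, 0, truth$noise_sd)
      data.frame(dose = d, fa = pmin(pmax(f, 1e-6), 1 - 1e-6))
    }
    list(single1 = single(truth$dm1, truth$m1),
         single2 = single(truth$dm2, truth$m2),
         combo = combo, truth = truth)
  })
}
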