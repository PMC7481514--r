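#' Generate a randomized complete block trial design
#'
#' Lays out a greenhouse NUE screening trial as a randomized complete block
#' design (RCBD): every genotype appears exactly once under every nitrogen
#' treatment within every replicate. Pots are arranged in rows of fixed
#' capacity; each replicate occupies a contiguous band of rows, nitrogen
#' treatments alternate between the rows of a band, and genotypes are
#' randomly allocated to positions within their treatment's rows. With the
#' default dimensions (76 genotypes, 2 N levels, 4 replicates, 38 pots per
#' row) this reproduces the 608-pot, 16-row greenhouse layout used for
#' perennial ryegrass NUE screening.
#'
#' @param n_genotypes number of genotypes (G).
#' @param n_treatments number of nitrogen levels (T).
#' @param n_replicates number of replicate blocks (R).
#' @param row_capacity pots per greenhouse row.
#' @param seed integer seed; the randomization is reproducible from it.
#' @param treatments numeric vector of length `n_treatments` giving the N
#'   concentrations in mM (default 0.5 and 5 mM for the two-level case).
#'
#' @return A `data.frame` with one row per pot and columns `pot_id`,
#'   `genotype` (factor `G01`, `G02`, ...), `treatment` (mM, numeric),
#'   `replicate` (integer block), `row_index`, `position_in_row`.
#'   Rows that a short final treatment block leaves unfilled are simply
#'   shorter; pot count is always exactly G x T x R.
#' @examples
#' d <- generate_design(76, 2, 4, 38, seed = 1)
#' nrow(d)                 # 608 pots
#' length(unique(d$row_index))  # 16 rows
#' @export
generate_design <- function(n_genotypes, n_treatments, n_replicates,
                            row_capacity, seed = 1L,
                            treatments = NULL) {
  G <- check_count(n_genotypes, "n_genotypes")
  T_ <- check_count(n_treatments, "n_treatments")
  R <- check_count(n_replicates, "n_replicates")
  cap <- check_count(row_capacity, "row_capacity")
  if (is.null(treatments)) {
    treatments <- if (T_ == 2L) c(0.5, 5) else seq_len(T_)
  }
  if (length(treatments) != T_) {
    stop("`treatments` must have length `n_treatments`", call. = FALSE)
  }

  geno_levels <- sprintf("G%02d", seq_len(G))
  rows_per_trt <- ceiling(G / cap)

  with_seed(seed, {
    out <- vector("list", R * T_)
    k <- 0L
    row_base <- 0L
    for (rep_i in seq_len(R)) {
      # one contiguous band of rows per replicate; treatments alternate
      # between consecutive rows of the band
      perms <- lapply(seq_len(T_), function(i) sample(geno_levels))
      for (trt_i in seq_len(T_)) {
        perm <- perms[[trt_i]]
        # the j-th row used by this treatment is the (j-1)*T + trt_i-th row
        # of the band, so rows cycle t1, t2, ..., tT, t1, t2, ...
        pos_global <- seq_len(G)
        chunk <- ceiling(pos_global / cap)          # which of this trt's rows
        row_index <- row_base + (chunk - 1L) * T_ + trt_i
        position <- pos_global - (chunk - 1L) * cap
        k <- k + 1L
        out[[k]] <- data.frame(
          genotype = perm,
          treatment = treatments[trt_i],
          replicate = rep_i,
          row_index = row_index,
          position_in_row = position,
          stringsAsFactors = FALSE
        )
      }
      row_base <- row_base + T_ * rows_per_trt
    }
    design <- do.call(rbind, out)
    design <- design[order(design$row_index, design$position_in_row), ]
    design$pot_id <- sprintf("P%04d", seq_len(nrow(design)))
    design$genotype <- factor(design$genotype, levels = geno_levels)
    rownames(design) <- NULL
    design[, c("pot_id", "genotype", "treatment", "replicate",
               "row_index", "position_in_row")]
  })
}
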