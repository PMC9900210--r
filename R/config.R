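# Model configuration and presets.

#' Model configuration
#'
#' Collects every architecture and loss hyper-parameter.  The `davis` and
#' `kiba` presets carry the benchmark-scale settings (padded lengths 1200
#' protein / 51 or 101 drug positions, channels 100/75/75, three or two
#' protein encoder blocks, large-kernel sizes (7,15,31) or (7,23,35));
#' `desk` is a reduced configuration sized for CPU-scale experiments and
#' tests, and `tiny` for unit tests.
#'
#' @param preset one of `"desk"`, `"tiny"`, `"davis"`, `"kiba"`.
#' @param ... named overrides of individual fields (see Details).
#'
#' @details Fields: `L_P`, `L_D` padded protein/drug lengths; `C_P`, `C_D`
#'   encoder channels; `C_S` shared channel size after fusion; `Pn`, `Dn`
#'   protein/drug encoder block counts; `kernel_lk` the three large-kernel
#'   1D convolution sizes (applied to the three convolution blocks in
#'   order); `kernel_2d` spatial-attention gate kernel; `groups` grouped-
#'   convolution group count (must divide `C_P`); `we_k`, `we_vocab_size`
#'   k-mer encoding parameters; `fp_radius`, `fp_bits` fingerprint
#'   parameters; `dropout` head dropout rate; `share_fc1` whether the two
#'   fusion branch projections share weights; `use_norm` enable per-channel
#'   length-axis normalization in the convolution blocks; `head_hidden`
#'   hidden widths of the affinity head; `S_scales` reported binding-region
#'   scales; `loss_w`, `loss_r`, `loss_epsilon`, `lambda_br` joint-loss
#'   parameters; `dataset_mode` affinity-label semantics.
#' @return An object of class `dta_config`.
#' @export
dta_config <- function(preset = c("desk", "tiny", "davis", "kiba"), ...) {
  preset <- match.arg(preset)
  cfg <- switch(preset,
    desk = list(L_P = 200L, L_D = 32L, C_P = 16L, C_D = 16L, C_S = 16L,
                Pn = 1L, Dn = 1L, kernel_lk = c(5L, 9L, 15L), kernel_2d = 3L,
                groups = 4L, fp_bits = 256L, head_hidden = c(128L, 32L)),
    tiny = list(L_P = 64L, L_D = 16L, C_P = 8L, C_D = 8L, C_S = 8L,
                Pn = 1L, Dn = 1L, kernel_lk = c(3L, 5L, 7L), kernel_2d = 3L,
                groups = 2L, fp_bits = 64L, head_hidden = c(32L, 16L)),
    davis = list(L_P = 1200L, L_D = 51L, C_P = 100L, C_D = 75L, C_S = 75L,
                 Pn = 3L, Dn = 2L, kernel_lk = c(7L, 15L, 31L), kernel_2d = 7L,
                 groups = 5L, fp_bits = 1024L, head_hidden = c(512L, 128L)),
    kiba = list(L_P = 1200L, L_D = 101L, C_P = 100L, C_D = 75L, C_S = 75L,
                Pn = 2L, Dn = 3L, kernel_lk = c(7L, 23L, 35L), kernel_2d = 3L,
                groups = 5L, fp_bits = 1024L, head_hidden = c(512L, 128L)))
  cfg <- c(cfg, list(we_k = 3L, we_vocab_size = 4096L, fp_radius = 2L,
                     f_atom = 14L, dropout = 0.1, share_fc1 = FALSE,
                     use_norm = TRUE, S_scales = c(5L, 10L, 15L),
                     loss_w = 3, loss_r = 1, loss_epsilon = 0.15,
                     lambda_br = 1, dataset_mode = "generic",
                     preset = preset))
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown dta_config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  validate_dta_config(structure(cfg, class = "dta_config"))
}

validate_dta_config <- function(cfg) {
  stopifnot(cfg$L_P >= 1, cfg$L_D >= 1, cfg$Pn >= 1, cfg$Dn >= 1)
  if (length(cfg$kernel_lk) != 3L) stop("kernel_lk must hold three kernel sizes")
  if (any(cfg$kernel_lk %% 2 == 0) || cfg$kernel_2d %% 2 == 0)
    stop("convolution kernel sizes must be odd for symmetric 'same' padding")
  if (cfg$C_P %% cfg$groups != 0L)
    stop("C_P (", cfg$C_P, ") must be divisible by groups (", cfg$groups, ")")
  if (cfg$dropout < 0 || cfg$dropout >= 1) stop("dropout must be in [0, 1)")
  rwing_params(cfg$loss_w, cfg$loss_r, cfg$loss_epsilon)  # validates ordering
  cfg
}

#' @export
print.dta_config <- function(x, ...) {
  cat("<dta_config> preset:", x$preset,
      sprintf("| L_P=%d L_D=%d C_P=%d C_D=%d C_S=%d Pn=%d Dn=%d\n",
              x$L_P, x$L_D, x$C_P, x$C_D, x$C_S, x$Pn, x$Dn),
      sprintf("  kernels LK=(%s) 2D=%d groups=%d | loss w=%g r=%g eps=%g lambda=%g\n",
              paste(x$kernel_lk, collapse = ","), x$kernel_2d, x$groups,
              x$loss_w, x$loss_r, x$loss_epsilon, x$lambda_br))
  invisible(x)
}

#' Training configuration
#'
#' Defaults follow the benchmark training recipe: AdamW, learning rate
#' 5e-4, weight decay 1e-3, batch size 16, dropout 0.1 (a model-config
#' field), with early stopping on validation MSE.
#'
#' @param lr learning rate (> 0).
#' @param weight_decay decoupled AdamW weight decay (>= 0, applied to
#'   weight matrices only).
#' @param batch_size minibatch size.
#' @param epochs maximum epochs.
#' @param patience early-stopping patience on validation MSE (set to
#'   `Inf` to disable).
#' @param seed integer RNG seed covering initialization, shuffling and
#'   dropout.
#' @param selection which parameters the returned model carries: the
#'   checkpoint with the best validation MSE (`"best"`, the benchmark
#'   protocol) or the parameters after the last epoch (`"final"`, e.g. when
#'   the quantity of interest is the fully trained response vector rather
#'   than held-out affinity error).
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr = 5e-4, weight_decay = 1e-3, batch_size = 16L,
                         epochs = 200L, patience = 20L, seed = 1L,
                         selection = c("best", "final")) {
  stopifnot(lr > 0, weight_decay >= 0, batch_size >= 1, epochs >= 0)
  structure(list(lr = lr, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = patience,
                 seed = as.integer(seed), selection = match.arg(selection)),
            class = "train_config")
}
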