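# 3D U-Net: configuration, weight initialization, parameter accounting,
# forward pass and the soft-Dice loss. The heavy lifting (im2col + GEMM
# convolutions, per-channel normalization, pooling, up-convolutions and the
# full backward pass) is implemented in C++.

#' Architecture configuration for the 3D U-Net
#'
#' The network has `levels` resolution levels (encoder levels plus the
#' bottleneck) and `base_width` feature maps at the top level; the channel
#' count doubles at each deeper level. Each block applies two 3x3x3
#' convolutions (bias-free, each followed by per-channel normalization and
#' ReLU); levels are connected by 2x2x2 max pooling (stride 2) going down
#' and 2x2x2 up-convolutions (with bias) going up, with skip concatenation.
#' A 1x1x1 two-channel head with bias feeds a voxelwise softmax over
#' background and chiasm classes. The default configuration (5 levels, base
#' width 10, channels 10-20-40-80-160) has exactly 2,206,482 trainable
#' parameters.
#'
#' @param levels integer >= 2, number of resolution levels incl. bottleneck.
#' @param base_width integer >= 1, feature maps at the first level.
#' @return An object of class `net_config`.
#' @export
net_config <- function(levels = 5L, base_width = 10L) {
  levels <- as.integer(levels)
  base_width <- as.integer(base_width)
  if (is.na(levels) || levels < 2L) stop("levels must be an integer >= 2")
  if (is.na(base_width) || base_width < 1L) stop("base_width must be >= 1")
  structure(list(levels = levels, base_width = base_width,
                 in_channels = 1L, out_channels = 2L),
            class = "net_config")
}

net_channels <- function(cfg) cfg$base_width * 2L^(seq_len(cfg$levels) - 1L)

he_uniform <- function(n, fan_in) {
  lim <- sqrt(6 / fan_in)
  stats::runif(n, -lim, lim)
}

init_block <- function(cin, cout, tag) {
  p <- list()
  p[[paste0(tag, "_conv1_w")]] <-
    array(he_uniform(27 * cin * cout, 27 * cin), dim = c(3, 3, 3, cin, cout))
  p[[paste0(tag, "_norm1_g")]] <- rep(1, cout)
  p[[paste0(tag, "_norm1_b")]] <- rep(0, cout)
  p[[paste0(tag, "_conv2_w")]] <-
    array(he_uniform(27 * cout * cout, 27 * cout), dim = c(3, 3, 3, cout, cout))
  p[[paste0(tag, "_norm2_g")]] <- rep(1, cout)
  p[[paste0(tag, "_norm2_b")]] <- rep(0, cout)
  p
}

#' Build a 3D U-Net with freshly initialized weights
#'
#' Convolution weights use He-uniform initialization; normalization scale
#' and shift start at one and zero; biases start at zero. The same seed and
#' configuration always produce identical weights.
#'
#' @param cfg a [net_config()].
#' @param seed integer seed for weight initialization.
#' @return An object of class `chiasm_unet` with elements `cfg` and
#'   `params` (named list of arrays in the canonical layer order).
#' @export
build_unet <- function(cfg = net_config(), seed = 1L) {
  stopifnot(inherits(cfg, "net_config"))
  ch <- net_channels(cfg)
  params <- with_seed(seed, {
    p <- list()
    for (l in seq_len(cfg$levels)) {
      cin <- if (l == 1L) 1L else ch[l - 1L]
      p <- c(p, init_block(cin, ch[l], paste0("enc", l)))
    }
    for (l in rev(seq_len(cfg$levels - 1L))) {
      tag <- paste0("dec", l)
      up <- list()
      up[[paste0(tag, "_up_w")]] <-
        array(he_uniform(8 * ch[l + 1L] * ch[l], 8 * ch[l + 1L]),
              dim = c(2, 2, 2, ch[l + 1L], ch[l]))
      up[[paste0(tag, "_up_b")]] <- rep(0, ch[l])
      p <- c(p, up, init_block(2L * ch[l], ch[l], tag))
    }
    p$head_w <- array(he_uniform(ch[1L] * 2, ch[1L]), dim = c(1, 1, 1, ch[1L], 2))
    p$head_b <- rep(0, 2)
    p
  })
  structure(list(cfg = cfg, params = params), class = "chiasm_unet")
}

#' Count the trainable parameters of a network
#'
#' Sums the lengths of every weight array actually held by the network.
#' Normalization layers contribute two learnable values per channel (scale
#' and shift); running statistics are not parameters.
#'
#' @param net a `chiasm_unet` (or a [net_config()], which is built first).
#' @return Integer parameter count.
#' @seealso [unet_parameter_count_formula()] for the closed-form arithmetic.
#' @export
unet_parameter_count <- function(net) {
  if (inherits(net, "net_config")) net <- build_unet(net, seed = 1L)
  stopifnot(inherits(net, "chiasm_unet"))
  sum(vapply(net$params, length, integer(1)))
}

#' Closed-form parameter arithmetic for the U-Net
#'
#' Evaluates the architecture's parameter count without instantiating any
#' weights: 27 * Cin * Cout per bias-free block convolution, 2 * C per
#' normalization layer, 8 * Cin * Cout + Cout per up-convolution, and
#' Cin * 2 + 2 for the softmax head. For the default configuration this
#' yields 2,206,482.
#'
#' @param cfg a [net_config()].
#' @return Integer parameter count.
#' @export
unet_parameter_count_formula <- function(cfg = net_config()) {
  stopifnot(inherits(cfg, "net_config"))
  ch <- net_channels(cfg)
  total <- 0
  for (l in seq_len(cfg$levels)) {
    cin <- if (l == 1L) 1L else ch[l - 1L]
    total <- total + 27 * cin * ch[l] + 2 * ch[l] +    # conv1 + norm1
      27 * ch[l] * ch[l] + 2 * ch[l]                   # conv2 + norm2
  }
  for (l in seq_len(cfg$levels - 1L)) {
    total <- total + 8 * ch[l + 1L] * ch[l] + ch[l] +  # up-convolution
      27 * (2 * ch[l]) * ch[l] + 2 * ch[l] +           # conv1 + norm1
      27 * ch[l] * ch[l] + 2 * ch[l]                   # conv2 + norm2
  }
  total + ch[1L] * 2 + 2                               # head
}

unet_check_input <- function(cfg, d) {
  m <- 2L^(cfg$levels - 1L)
  if (any(d %% m != 0L))
    stop(sprintf("input sides must be multiples of %d, got %s",
                 m, paste(d, collapse = "x")))
}

#' Forward pass of the U-Net
#'
#' Returns the two-channel voxelwise softmax output; the foreground channel
#' is the per-voxel probability of belonging to the optic chiasm. Output
#' shape equals input shape; sides must be multiples of
#' `2^(levels - 1)` (16 for the default configuration).
#'
#' @param net a `chiasm_unet`.
#' @param x a volume or 3D array of intensities.
#' @return A `chiasm_probmap`: list with 3D arrays `fg` and `bg` summing to
#'   1 per voxel.
#' @export
unet_forward <- function(net, x) {
  stopifnot(inherits(net, "chiasm_unet"))
  arr <- as_volume_array(x)
  d <- dim(arr)
  unet_check_input(net$cfg, d)
  out <- .unet_forward_cpp(net$params, as.numeric(arr), as.integer(d),
                           net$cfg$levels, net$cfg$base_width)
  structure(list(fg = array(out$fg, d), bg = array(out$bg, d)),
            class = "chiasm_probmap")
}

#' @export
print.chiasm_probmap <- function(x, ...) {
  cat(sprintf("<chiasm_probmap> %s voxels, fg range [%.4g, %.4g]\n",
              paste(dim(x$fg), collapse = "x"), min(x$fg), max(x$fg)))
  invisible(x)
}

#' @export
print.chiasm_unet <- function(x, ...) {
  cat(sprintf("<chiasm_unet> levels %d, base width %d, %s parameters\n",
              x$cfg$levels, x$cfg$base_width,
              format(unet_parameter_count(x), big.mark = ",")))
  invisible(x)
}

#' Soft-Dice loss
#'
#' `1 - (2 * sum(p * g) + s) / (sum(p) + sum(g) + s)` over the foreground
#' probability `p` and binary target `g`, with smoothing `s` guarding the
#' empty-target case. The loss lies in \[0, 1\] and is 0 (up to `s`) iff the
#' prediction matches the target exactly.
#'
#' @param pred a `chiasm_probmap` or a 3D array of foreground probabilities.
#' @param target a binary mask of the same shape.
#' @param smooth smoothing term, default `1e-5`.
#' @return The loss value.
#' @export
dice_loss <- function(pred, target, smooth = 1e-5) {
  p <- if (inherits(pred, "chiasm_probmap")) pred$fg else as.array(pred)
  g <- as_mask_array(target)
  if (!identical(dim(p), dim(g))) stop("shape mismatch between pred and target")
  1 - (2 * sum(p * g) + smooth) / (sum(p) + sum(g) + smooth)
}

#' Save / load a network checkpoint
#'
#' The checkpoint is the package's native serialized R object (weights plus
#' configuration); alongside it an architecture JSON (configuration and
#' parameter count) is written for audit.
#'
#' @param net a `chiasm_unet`.
#' @param path destination `.rds` file; the JSON goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(net, path) {
  stopifnot(inherits(net, "chiasm_unet"))
  saveRDS(net, path)
  meta <- list(levels = net$cfg$levels, base_width = net$cfg$base_width,
               in_channels = 1L, out_channels = 2L,
               parameter_count = unet_parameter_count(net))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  net <- readRDS(path)
  if (!inherits(net, "chiasm_unet")) stop("checkpoint does not hold a chiasm_unet")
  net
}
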