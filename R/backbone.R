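#' Build a per-instance convolutional backbone
#'
#' Constructs the feature extractor that maps a preprocessed 3-channel image
#' to a spatial feature map of shape `C x H x W`. Two variants are available:
#'
#' * `"resnet34"` — the standard 34-layer residual design with the final
#'   fully-connected layer removed (`C = 512`; total stride 32, so a
#'   256x256 input yields an 8x8 map). ImageNet-pretrained weights may be
#'   supplied via `pretrained_path` (an RDS file holding a parameter list of
#'   the same structure as `backbone_params()` returns); random He
#'   initialisation is used otherwise.
#' * `"tinycnn"` — a compact test-scale backbone: four blocks of
#'   \[3x3 conv (bias-free), batch norm, ReLU\] each with stride 2
#'   (`C = 64`; a 64x64 input yields a 4x4 map). Used throughout the test
#'   suite and the synthetic experiments so nothing needs to be downloaded.
#'
#' @param variant `"resnet34"` or `"tinycnn"`.
#' @param pretrained_path optional path to an RDS parameter list to load.
#' @param seed optional integer; when given, initialisation is drawn from the
#'   `"init"` sub-stream of this seed (see [substream_seed()]).
#' @return A backbone object (nested layer list) with attribute `out_channels`.
#' @export
#' @examples
#' bb <- build_backbone("tinycnn", seed = 1)
#' x <- array(rnorm(2 * 64 * 64 * 3), dim = c(64, 64, 3, 2))
#' dim(extract_features(bb, x))  # 4 4 64 2
build_backbone <- function(variant = c("tinycnn", "resnet34"),
                           pretrained_path = NULL, seed = NULL) {
  variant <- match.arg(variant)
  build <- function() {
    if (variant == "tinycnn") {
      ch <- c(3L, 8L, 16L, 32L, 64L)
      blocks <- vector("list", 12L)
      for (i in 1:4) {
        blocks[[3 * i - 2]] <- nn_conv(ch[i], ch[i + 1], 3L, stride = 2L,
                                       pad = 1L, bias = FALSE)
        blocks[[3 * i - 1]] <- nn_bn(ch[i + 1])
        blocks[[3 * i]] <- nn_relu()
      }
      net <- do.call(nn_seq, blocks)
      attr(net, "out_channels") <- 64L
      net
    } else {
      stage <- function(cin, cout, n, stride) {
        bl <- vector("list", n)
        bl[[1]] <- nn_resblock(cin, cout, stride)
        for (i in seq_len(n - 1)) bl[[i + 1]] <- nn_resblock(cout, cout, 1L)
        bl
      }
      net <- do.call(nn_seq, c(
        list(nn_conv(3L, 64L, 7L, stride = 2L, pad = 3L, bias = FALSE),
             nn_bn(64L), nn_relu(), nn_maxpool(3L, 2L, 1L)),
        stage(64L, 64L, 3L, 1L),
        stage(64L, 128L, 4L, 2L),
        stage(128L, 256L, 6L, 2L),
        stage(256L, 512L, 3L, 2L)))
      attr(net, "out_channels") <- 512L
      net
    }
  }
  net <- if (is.null(seed)) build() else with_stream(seed, "init", build())
  if (!is.null(pretrained_path)) {
    p <- readRDS(pretrained_path)
    net <- net_set_params(net, p)
  }
  attr(net, "variant") <- variant
  net
}

#' @rdname build_backbone
#' @param backbone a backbone built by `build_backbone()`.
#' @export
backbone_params <- function(backbone) net_params(backbone)

#' Extract per-instance spatial feature maps
#'
#' Runs the backbone over a flattened batch of instances. The operation is
#' instance-wise: permuting inputs permutes outputs identically.
#'
#' @param backbone a backbone from [build_backbone()].
#' @param images numeric array `[H_img, W_img, 3, M]` of preprocessed images.
#' @param training logical; batch-norm uses batch statistics when `TRUE`,
#'   running statistics when `FALSE` (deterministic evaluation).
#' @return Numeric array `[H, W, C, M]` of feature maps.
#' @export
extract_features <- function(backbone, images, training = FALSE) {
  stopifnot(length(dim(images)) == 4L, dim(images)[3L] == 3L)
  layer_fwd(backbone, images, training)$y
}
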