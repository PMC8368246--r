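## A compact CPU implementation of a 3D dense V-Net: dense feature
## stacks at two resolution levels, dilated convolutions, V-Net style
## down/upsampling with a skip connection forwarding full-resolution
## features to the head, batch-wise spatial dropout, soft-max output.
## Forward and backward passes run through the package's C++ kernels;
## the computational graph is a static list of nodes.

#' Dense V-Net configuration
#'
#' Channel widths are configurable so that a tiny CPU variant exists;
#' the defaults describe the desk-scale model. Input channels default to
#' 2 (in-phase + out-of-phase); `n_classes` includes the background.
#'
#' @param input_channels number of input channels (default 2, IP + OOP).
#' @param n_classes number of output classes including background.
#' @param init_features channels of the stem convolution.
#' @param growth per-level dense-block growth rate (features added per
#'   dense layer), length = number of levels (2).
#' @param block_depth per-level number of dense layers.
#' @param dilations dilation rate of successive dense layers within a
#'   block (recycled as needed).
#' @param bottleneck per-level channels of the 1x1x1 compression conv
#'   closing each dense block.
#' @param head_features channels of the pre-output convolution.
#' @param dropout batch-wise spatial dropout rate on the concatenated
#'   skip features (applied at training time only).
#' @param pool integer length-3 down/upsampling factors between the two
#'   resolution levels.
#' @return a `DenseVNetConfig` list.
#' @export
denseVNetConfig <- function(input_channels = 2L, n_classes = 15L,
                            init_features = 8L, growth = c(4L, 8L),
                            block_depth = c(2L, 2L), dilations = c(1L, 2L),
                            bottleneck = c(8L, 16L), head_features = 8L,
                            dropout = 0.1, pool = c(2L, 2L, 2L)) {
  stopifnot(n_classes >= 2, input_channels >= 1, length(growth) == 2,
            length(block_depth) == 2, length(bottleneck) == 2,
            dropout >= 0, dropout < 1, length(pool) == 3, all(pool >= 1))
  structure(list(input_channels = as.integer(input_channels),
                 n_classes = as.integer(n_classes),
                 init_features = as.integer(init_features),
                 growth = as.integer(growth),
                 block_depth = as.integer(block_depth),
                 dilations = as.integer(dilations),
                 bottleneck = as.integer(bottleneck),
                 head_features = as.integer(head_features),
                 dropout = dropout, pool = as.integer(pool)),
            class = "DenseVNetConfig")
}

## He-initialised conv node
.convNode <- function(input, cin, cout, k, dilation = 1L,
                      activation = "relu") {
  w <- array(rnorm(k^3 * cin * cout, 0, sqrt(2 / (k^3 * cin))),
             c(k, k, k, cin, cout))
  list(op = "conv", inputs = input, w = w, b = numeric(cout), k = k,
       cin = cin, cout = cout, dilation = as.integer(dilation),
       activation = activation)
}

#' Build a dense V-Net model
#'
#' Constructs the node graph (stem convolution, two dense blocks with
#' dilated convolutions and 1x1x1 compressions, pooling/upsampling,
#' skip concatenation, spatial dropout, head) with He-initialised
#' weights. The parameter count is a pure function of the configuration.
#'
#' @param config a [denseVNetConfig()].
#' @param seed integer seed for the weight initialisation.
#' @return a `denseVNet` model object (list with `config`, `nodes`,
#'   `n_params`; `lookup` and `landmarks` slots are attached by
#'   [trainDenseVNet()]).
#' @export
buildDenseVNet <- function(config = denseVNetConfig(), seed = 1L) {
  stopifnot(inherits(config, "DenseVNetConfig"))
  .withSeed(seed, {
    nodes <- list()
    add <- function(node) {
      nodes[[length(nodes) + 1L]] <<- node
      length(nodes)
    }
    dil <- function(j) config$dilations[(j - 1L) %% length(config$dilations) + 1L]
    inp <- add(list(op = "input", inputs = integer(),
                    cout = config$input_channels))
    stem <- add(.convNode(inp, config$input_channels, config$init_features,
                          3L))
    denseBlock <- function(entry, cin, level) {
      members <- entry
      chans <- cin
      for (j in seq_len(config$block_depth[level])) {
        cc <- add(list(op = "concat", inputs = members,
                       cout = chans))
        cv <- add(.convNode(cc, chans, config$growth[level], 3L,
                            dilation = dil(j)))
        members <- c(members, cv)
        chans <- chans + config$growth[level]
      }
      cc <- add(list(op = "concat", inputs = members, cout = chans))
      add(.convNode(cc, chans, config$bottleneck[level], 1L))
    }
    skip1 <- denseBlock(stem, config$init_features, 1L)
    pool <- add(list(op = "pool", inputs = skip1, f = config$pool,
                     cout = config$bottleneck[1]))
    deep <- denseBlock(pool, config$bottleneck[1], 2L)
    up <- add(list(op = "up", inputs = deep, f = config$pool,
                   cout = config$bottleneck[2]))
    cat_ch <- config$bottleneck[1] + config$bottleneck[2]
    cc <- add(list(op = "concat", inputs = c(skip1, up), cout = cat_ch))
    dr <- add(list(op = "dropout", inputs = cc, rate = config$dropout,
                   cout = cat_ch))
    head <- add(.convNode(dr, cat_ch, config$head_features, 3L))
    out <- add(.convNode(head, config$head_features, config$n_classes, 1L,
                         activation = "linear"))
    n_params <- sum(vapply(nodes, function(nd)
      if (nd$op == "conv") length(nd$w) + length(nd$b) else 0L, numeric(1)))
    structure(list(config = config, nodes = nodes, out_node = out,
                   n_params = n_params, lookup = NULL, landmarks = NULL),
              class = "denseVNet")
  })
}

#' @export
print.denseVNet <- function(x, ...) {
  cat(sprintf("denseVNet: %d nodes, %d parameters, %d classes, %d input channels\n",
              length(x$nodes), x$n_params, x$config$n_classes,
              x$config$input_channels))
  invisible(x)
}

## check spatial shape against total downsampling
.checkWindow <- function(model, d) {
  f <- model$config$pool
  if (any(d[1:3] %% f != 0))
    stop(sprintf("spatial shape (%s) must be divisible by the downsampling factors (%s)",
                 paste(d[1:3], collapse = "x"), paste(f, collapse = "x")),
         call. = FALSE)
  invisible(TRUE)
}

## forward pass; x is (X,Y,Z,Cin). Returns activations per node.
## train=TRUE draws (seeded by caller's RNG) spatial dropout masks.
.netForward <- function(model, x, train = FALSE) {
  d <- dim(x)
  .checkWindow(model, d)
  if (d[4] != model$config$input_channels)
    stop("input channel mismatch", call. = FALSE)
  acts <- vector("list", length(model$nodes))
  aux <- vector("list", length(model$nodes))
  for (i in seq_along(model$nodes)) {
    nd <- model$nodes[[i]]
    acts[[i]] <- switch(nd$op,
      input = x,
      conv = {
        a <- acts[[nd$inputs]]
        da <- dim(a)
        y <- .conv3dForward(as.numeric(a), da[1:3], as.numeric(nd$w),
                            nd$b, nd$k, nd$cin, nd$cout, nd$dilation)
        y <- array(y, c(da[1:3], nd$cout))
        if (nd$activation == "relu") y[y < 0] <- 0
        y
      },
      concat = {
        parts <- acts[nd$inputs]
        da <- dim(parts[[1]])
        array(unlist(parts, use.names = FALSE),
              c(da[1:3], sum(vapply(parts, function(p) dim(p)[4],
                                    numeric(1)))))
      },
      pool = {
        a <- acts[[nd$inputs]]
        da <- dim(a)
        array(.avgPoolForward(as.numeric(a), da, nd$f),
              c(da[1:3] %/% nd$f, da[4]))
      },
      up = {
        a <- acts[[nd$inputs]]
        da <- dim(a)
        array(.upsampleForward(as.numeric(a), da, nd$f),
              c(da[1:3] * nd$f, da[4]))
      },
      dropout = {
        a <- acts[[nd$inputs]]
        if (train && nd$rate > 0) {
          keep <- runif(dim(a)[4]) >= nd$rate
          if (!any(keep)) keep[sample.int(length(keep), 1)] <- TRUE
          scale <- keep / mean(keep)
          aux[[i]] <- scale
          sweep(a, 4, scale, "*")
        } else a
      },
      stop("unknown op: ", nd$op))
  }
  list(acts = acts, aux = aux)
}

## backward pass from dlogits; returns list of per-node list(gw, gb)
.netBackward <- function(model, fwd, dlogits) {
  n <- length(model$nodes)
  grads <- vector("list", n)
  pgrads <- vector("list", n)
  grads[[model$out_node]] <- dlogits
  for (i in rev(seq_len(n))) {
    g <- grads[[i]]
    if (is.null(g)) next
    nd <- model$nodes[[i]]
    if (nd$op == "input") next
    if (nd$op == "conv") {
      a <- fwd$acts[[nd$inputs]]
      da <- dim(a)
      if (nd$activation == "relu") g <- g * (fwd$acts[[i]] > 0)
      bw <- .conv3dBackward(as.numeric(a), da[1:3], as.numeric(nd$w),
                            as.numeric(g), nd$k, nd$cin, nd$cout,
                            nd$dilation)
      pgrads[[i]] <- list(gw = array(bw$gw, dim(nd$w)), gb = bw$gb)
      gi <- array(bw$gx, da)
      grads[[nd$inputs]] <- if (is.null(grads[[nd$inputs]])) gi else
        grads[[nd$inputs]] + gi
    } else if (nd$op == "concat") {
      off <- 0L
      for (src in nd$inputs) {
        cs <- dim(fwd$acts[[src]])[4]
        gi <- g[, , , off + seq_len(cs), drop = FALSE]
        grads[[src]] <- if (is.null(grads[[src]])) gi else
          grads[[src]] + gi
        off <- off + cs
      }
    } else if (nd$op == "pool") {
      da <- dim(fwd$acts[[nd$inputs]])
      gi <- array(.avgPoolBackward(as.numeric(g), da, nd$f), da)
      grads[[nd$inputs]] <- if (is.null(grads[[nd$inputs]])) gi else
        grads[[nd$inputs]] + gi
    } else if (nd$op == "up") {
      da <- dim(fwd$acts[[nd$inputs]])
      gi <- array(.upsampleBackward(as.numeric(g), da, nd$f), da)
      grads[[nd$inputs]] <- if (is.null(grads[[nd$inputs]])) gi else
        grads[[nd$inputs]] + gi
    } else if (nd$op == "dropout") {
      gi <- if (is.null(fwd$aux[[i]])) g else sweep(g, 4, fwd$aux[[i]], "*")
      grads[[nd$inputs]] <- if (is.null(grads[[nd$inputs]])) gi else
        grads[[nd$inputs]] + gi
    }
    grads[[i]] <- NULL
  }
  pgrads
}

## numerically stable voxelwise soft-max over the channel axis
.softmax4d <- function(logits) {
  d <- dim(logits)
  m <- matrix(logits, ncol = d[4])
  m <- m - m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  e <- exp(m)
  array(e / rowSums(e), d)
}

#' Dice hinge loss
#'
#' Per-foreground-class soft Dice loss (`1 - 2|P.T|/(|P| + |T|)`), with
#' per-class contributions below `hinge_margin` clamped to zero, averaged
#' over the non-clamped foreground classes present in the target. This
#' limits the bias toward predicting the dominant background. Returns 0
#' when all classes are clamped; when the target window contains no
#' foreground at all, the background class is scored instead.
#'
#' @param probabilities 4D array (X, Y, Z, n_classes) of soft-max
#'   probabilities.
#' @param target integer array (X, Y, Z) of class indices in
#'   `0..n_classes-1`.
#' @param hinge_margin clamp threshold (default 0.1); 0 gives the plain
#'   soft Dice loss.
#' @return scalar loss with attribute `per_class` (named soft Dice per
#'   scored class).
#' @export
diceHingeLoss <- function(probabilities, target, hinge_margin = 0.1) {
  r <- .diceLossGrad(probabilities, target, hinge_margin,
                     want_grad = FALSE)
  structure(r$loss, per_class = r$dice)
}

## loss + gradient wrt probabilities; classes are 0-based indices
.diceLossGrad <- function(prob, target, margin, want_grad = TRUE) {
  d <- dim(prob)
  if (anyNA(prob) || any(!is.finite(prob)))
    return(list(loss = NaN, dice = numeric(0),
                gprob = if (want_grad) array(0, d)))
  nc <- d[4]
  nvox <- prod(d[1:3])
  pm <- matrix(prob, nrow = nvox, ncol = nc)
  tv <- as.integer(target)
  counts <- tabulate(tv + 1L, nbins = nc)
  classes <- which(counts[-1] > 0)        # foreground classes present
  if (length(classes) == 0L) classes <- 0L else classes <- classes
  gp <- if (want_grad) matrix(0, nrow = nvox, ncol = nc) else NULL
  dice <- numeric(0)
  active <- 0L
  loss <- 0
  contrib <- list()
  for (cl in classes) {
    p <- pm[, cl + 1L]
    t <- as.numeric(tv == cl)
    Sp <- sum(p); St <- sum(t); I <- sum(p * t)
    den <- Sp + St
    if (den <= 0) next
    dc <- 2 * I / den
    dice[as.character(cl)] <- dc
    lc <- 1 - dc
    if (lc < margin) next                  # hinge: clamped to 0
    active <- active + 1L
    loss <- loss + lc
    if (want_grad)
      contrib[[length(contrib) + 1L]] <-
        list(cl = cl, grad = -2 * (t * den - I) / den^2)
  }
  if (active > 0L) {
    loss <- loss / active
    if (want_grad)
      for (ct in contrib)
        gp[, ct$cl + 1L] <- gp[, ct$cl + 1L] + ct$grad / active
  } else loss <- 0
  list(loss = loss, dice = dice,
       gprob = if (want_grad) array(gp, d) else NULL)
}

## loss and gradient wrt logits (through the soft-max Jacobian)
.lossOnLogits <- function(logits, target, margin) {
  prob <- .softmax4d(logits)
  r <- .diceLossGrad(prob, target, margin)
  d <- dim(prob)
  nvox <- prod(d[1:3])
  pm <- matrix(prob, nrow = nvox)
  gm <- matrix(r$gprob, nrow = nvox)
  dot <- rowSums(pm * gm)
  dz <- pm * (gm - dot)
  list(loss = r$loss, dice = r$dice, dlogits = array(dz, d))
}

#' Training configuration
#'
#' Defaults mirror the published recipe at desk scale: Adam with
#' learning rate 0.001, ReLU activations, l2 weight decay 1e-5, Dice
#' hinge loss, uniform window sampling with 3 samples per volume and
#' batch size 3; the spatial window is configurable (the full-scale
#' setting used 360 x 240 x 32).
#'
#' @param learning_rate Adam learning rate.
#' @param l2_decay l2 regularization coefficient.
#' @param batch_size windows per gradient step.
#' @param samples_per_volume windows drawn per volume per epoch.
#' @param window integer length-3 spatial window.
#' @param max_iterations iteration cap.
#' @param eval_every validation cadence (iterations).
#' @param patience number of consecutive evaluations without improvement
#'   of the validation Dice before stopping (plateau rule).
#' @param min_delta minimal Dice improvement counted as progress.
#' @param loss `"dice_hinge"` (default) or `"dice"` (margin 0).
#' @param hinge_margin clamp threshold of the Dice hinge.
#' @param seed master seed; every random draw in training flows from it.
#' @return a `TrainingConfig` list.
#' @export
trainingConfig <- function(learning_rate = 0.001, l2_decay = 1e-5,
                           batch_size = 3L, samples_per_volume = 3L,
                           window = c(48L, 48L, 8L),
                           max_iterations = 500L, eval_every = 25L,
                           patience = 6L, min_delta = 1e-3,
                           loss = c("dice_hinge", "dice"),
                           hinge_margin = 0.1, seed = 1L) {
  loss <- match.arg(loss)
  stopifnot(learning_rate > 0, l2_decay >= 0, batch_size >= 1,
            length(window) == 3, all(window >= 4), max_iterations >= 1)
  structure(list(learning_rate = learning_rate, l2_decay = l2_decay,
                 batch_size = as.integer(batch_size),
                 samples_per_volume = as.integer(samples_per_volume),
                 window = as.integer(window),
                 max_iterations = as.integer(max_iterations),
                 eval_every = as.integer(eval_every),
                 patience = as.integer(patience), min_delta = min_delta,
                 loss = loss,
                 hinge_margin = if (loss == "dice") 0 else hinge_margin,
                 seed = as.integer(seed)), class = "TrainingConfig")
}

#' Assemble a training sample from a Dixon volume and mask
#'
#' Stacks the in-phase and out-of-phase images (optionally histogram
#' standardized) into the network input and normalizes mask labels to
#' contiguous indices.
#'
#' @param volume a [DixonVolume-class].
#' @param mask a [SegmentationMask-class].
#' @param scheme the [MuscleLabelScheme-class].
#' @param landmarks optional per-channel list of [fitLandmarks()] output
#'   (`list(ip = ..., oop = ...)`).
#' @return list with `x` (X, Y, Z, 2 array), `y` (integer index array)
#'   and `lookup`.
#' @export
makeTrainingSample <- function(volume, mask, scheme = defaultLabelScheme(),
                               landmarks = NULL) {
  ip <- inPhase(volume); oop <- outOfPhase(volume)
  if (!is.null(landmarks)) {
    ip <- histogramStandardize(ip, landmarks$ip)
    oop <- histogramStandardize(oop, landmarks$oop)
  }
  nl <- normalizeLabels(mask, scheme)
  d <- dim(ip)
  x <- array(c(ip, oop), c(d, 2L))
  ## scale intensities to unit order of magnitude
  x <- x / max(abs(x))
  list(x = x, y = nl$mask@labels, lookup = nl$lookup)
}

## hard mean foreground Dice between an index map and prediction
.meanForegroundDice <- function(pred_idx, true_idx, n_classes) {
  ds <- numeric(0)
  for (cl in seq_len(n_classes - 1L)) {
    St <- sum(true_idx == cl)
    if (St == 0) next
    Sp <- sum(pred_idx == cl)
    I <- sum(pred_idx == cl & true_idx == cl)
    ds <- c(ds, 2 * I / (Sp + St))
  }
  if (length(ds)) mean(ds) else NA_real_
}

#' Train a dense V-Net
#'
#' Uniform window sampling over the training volumes, Adam updates with
#' l2 regularization, Dice hinge loss, periodic validation on
#' non-augmented volumes with a plateau stopping rule. Deterministic
#' given the seed (single-threaded). Training aborts with diagnostics if
#' the loss becomes non-finite.
#'
#' @param model a [buildDenseVNet()] model.
#' @param train_data list of samples from [makeTrainingSample()].
#' @param val_data validation samples (defaults to `train_data`, i.e.
#'   the non-augmented raw volumes convention).
#' @param config a [trainingConfig()].
#' @param verbose print progress every evaluation.
#' @param restarts maximum number of fresh re-initializations attempted
#'   when training stalls (best validation Dice below `restart_dice` at
#'   the plateau or iteration cap). Small-window Dice-loss training can
#'   settle in a left/right label-assignment local optimum where
#'   confident soft-max outputs leave near-zero gradients; a restart
#'   from new random weights escapes it. 0 (default) disables restarts.
#' @param restart_dice validation-Dice level below which a restart is
#'   attempted.
#' @return the trained model, with `history` (data.frame of iteration,
#'   loss, validation Dice), `best_val_dice`, `attempts` and `lookup`
#'   attached.
#' @export
trainDenseVNet <- function(model, train_data, val_data = NULL,
                           config = trainingConfig(), verbose = FALSE,
                           restarts = 0L, restart_dice = 0.8) {
  fit <- .trainCore(model, train_data, val_data, config, verbose)
  fit$attempts <- 1L
  a <- 0L
  while (fit$best_val_dice < restart_dice && a < restarts) {
    a <- a + 1L
    if (verbose)
      message(sprintf("validation Dice %.3f below %.2f: restart %d",
                      fit$best_val_dice, restart_dice, a))
    cfg_a <- config
    cfg_a$seed <- config$seed + 104729L * a
    fresh <- buildDenseVNet(model$config, seed = config$seed + 7919L * a)
    fit_a <- .trainCore(fresh, train_data, val_data, cfg_a, verbose)
    if (fit_a$best_val_dice > fit$best_val_dice) {
      at <- a + 1L
      fit <- fit_a
      fit$attempts <- at
    }
  }
  fit
}

.trainCore <- function(model, train_data, val_data = NULL,
                       config = trainingConfig(), verbose = FALSE) {
  stopifnot(inherits(model, "denseVNet"), length(train_data) > 0)
  if (is.null(val_data)) val_data <- train_data
  win <- config$window
  .checkWindow(model, win)
  for (s in train_data) {
    if (any(dim(s$x)[1:3] < win))
      stop("window larger than a training volume", call. = FALSE)
  }
  ## Adam state
  conv_ids <- which(vapply(model$nodes, function(nd) nd$op == "conv",
                           logical(1)))
  st <- lapply(conv_ids, function(i)
    list(mw = array(0, dim(model$nodes[[i]]$w)),
         vw = array(0, dim(model$nodes[[i]]$w)),
         mb = numeric(length(model$nodes[[i]]$b)),
         vb = numeric(length(model$nodes[[i]]$b))))
  names(st) <- as.character(conv_ids)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- config$learning_rate
  history <- list()
  best <- -Inf; stale <- 0L
  evalDice <- function() {
    ds <- vapply(val_data, function(s) {
      seg <- .segmentArray(model, s$x)
      .meanForegroundDice(seg$idx, s$y, model$config$n_classes)
    }, numeric(1))
    mean(ds, na.rm = TRUE)
  }
  .withSeed(config$seed, {
    for (it in seq_len(config$max_iterations)) {
      agg <- NULL
      loss_it <- 0
      for (bi in seq_len(config$batch_size)) {
        s <- train_data[[sample.int(length(train_data), 1L)]]
        d <- dim(s$x)
        o <- vapply(1:3, function(a)
          sample.int(d[a] - win[a] + 1L, 1L), integer(1))
        xi <- s$x[o[1]:(o[1] + win[1] - 1L), o[2]:(o[2] + win[2] - 1L),
                  o[3]:(o[3] + win[3] - 1L), , drop = FALSE]
        yi <- s$y[o[1]:(o[1] + win[1] - 1L), o[2]:(o[2] + win[2] - 1L),
                  o[3]:(o[3] + win[3] - 1L)]
        fwd <- .netForward(model, xi, train = TRUE)
        lo <- .lossOnLogits(fwd$acts[[model$out_node]], yi,
                            config$hinge_margin)
        if (!is.finite(lo$loss))
          stop(sprintf("non-finite loss at iteration %d (window origin %s)",
                       it, paste(o, collapse = ",")), call. = FALSE)
        loss_it <- loss_it + lo$loss / config$batch_size
        pg <- .netBackward(model, fwd, lo$dlogits)
        if (is.null(agg)) {
          agg <- pg
        } else {
          for (i in conv_ids) {
            if (is.null(pg[[i]])) next
            agg[[i]]$gw <- agg[[i]]$gw + pg[[i]]$gw
            agg[[i]]$gb <- agg[[i]]$gb + pg[[i]]$gb
          }
        }
      }
      t_adam <- it
      for (i in conv_ids) {
        nd <- model$nodes[[i]]
        gw <- agg[[i]]$gw / config$batch_size + config$l2_decay * nd$w
        gb <- agg[[i]]$gb / config$batch_size
        s_i <- st[[as.character(i)]]
        s_i$mw <- b1 * s_i$mw + (1 - b1) * gw
        s_i$vw <- b2 * s_i$vw + (1 - b2) * gw^2
        s_i$mb <- b1 * s_i$mb + (1 - b1) * gb
        s_i$vb <- b2 * s_i$vb + (1 - b2) * gb^2
        mhat <- s_i$mw / (1 - b1^t_adam); vhat <- s_i$vw / (1 - b2^t_adam)
        nd$w <- nd$w - lr * mhat / (sqrt(vhat) + eps)
        mhat <- s_i$mb / (1 - b1^t_adam); vhat <- s_i$vb / (1 - b2^t_adam)
        nd$b <- nd$b - lr * mhat / (sqrt(vhat) + eps)
        model$nodes[[i]] <- nd
        st[[as.character(i)]] <- s_i
      }
      if (it %% config$eval_every == 0L || it == config$max_iterations) {
        vd <- evalDice()
        history[[length(history) + 1L]] <-
          data.frame(iteration = it, loss = loss_it, val_dice = vd)
        if (verbose)
          message(sprintf("iter %d  loss %.4f  val fg Dice %.4f", it,
                          loss_it, vd))
        if (vd > best + config$min_delta) {
          best <- vd; stale <- 0L
        } else {
          stale <- stale + 1L
          if (stale >= config$patience) break
        }
      } else {
        history[[length(history) + 1L]] <-
          data.frame(iteration = it, loss = loss_it, val_dice = NA_real_)
      }
    }
  })
  model$history <- do.call(rbind, history)
  model$lookup <- train_data[[1]]$lookup
  model$best_val_dice <- best
  model
}

## forward + soft-max + argmax on a prepared input array (pads to the
## downsampling multiple and crops back)
.segmentArray <- function(model, x) {
  d <- dim(x)
  f <- model$config$pool
  pad <- (f - d[1:3] %% f) %% f
  if (any(pad > 0)) {
    xp <- array(0, c(d[1:3] + pad, d[4]))
    xp[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), ] <- x
    x <- xp
  }
  fwd <- .netForward(model, x, train = FALSE)
  prob <- .softmax4d(fwd$acts[[model$out_node]])
  prob <- prob[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), ,
               drop = FALSE]
  pm <- matrix(prob, ncol = dim(prob)[4])
  idx <- max.col(pm, ties.method = "first") - 1L
  list(prob = prob, idx = array(as.integer(idx), d[1:3]))
}

#' Segment a Dixon scan with a trained model
#'
#' Runs the network on the stacked in-phase/out-of-phase input and
#' returns voxelwise class probabilities (soft-max; summing to 1) plus
#' the hard label map mapped back through the training label lookup.
#' Volumes whose extent exceeds `window` are processed in overlapping
#' tiles whose probabilities are averaged.
#'
#' @param model a trained `denseVNet` (with `lookup` attached).
#' @param ip,oop 3D arrays (in-phase and out-of-phase), equal shape.
#' @param spacing voxel spacing of the output mask.
#' @param window optional integer length-3 tiling window; default
#'   processes the whole volume in one pass.
#' @return list with `prob` (4D array) and `mask`
#'   ([SegmentationMask-class] in original label values).
#' @export
segmentDixon <- function(model, ip, oop, spacing = c(1, 1, 1),
                         window = NULL) {
  .checkSameShape(ip, oop, "ip/oop")
  d <- dim(ip)
  x <- array(c(ip, oop), c(d, 2L))
  x <- x / max(abs(x))
  if (is.null(window) || all(d <= window)) {
    seg <- .segmentArray(model, x)
  } else {
    nc <- model$config$n_classes
    acc <- array(0, c(d, nc))
    cnt <- array(0, d)
    stride <- pmax(window %/% 2L, 1L)
    starts <- function(n, w, s) {
      if (n <= w) return(1L)
      v <- seq(1L, n - w, by = s)
      unique(c(v, n - w + 1L))
    }
    for (ox in starts(d[1], window[1], stride[1]))
      for (oy in starts(d[2], window[2], stride[2]))
        for (oz in starts(d[3], window[3], stride[3])) {
          ix <- ox:(min(ox + window[1] - 1L, d[1]))
          iy <- oy:(min(oy + window[2] - 1L, d[2]))
          iz <- oz:(min(oz + window[3] - 1L, d[3]))
          seg_t <- .segmentArray(model, x[ix, iy, iz, , drop = FALSE])
          acc[ix, iy, iz, ] <- acc[ix, iy, iz, ] + seg_t$prob
          cnt[ix, iy, iz] <- cnt[ix, iy, iz] + 1
        }
    prob <- acc / as.vector(cnt)
    pm <- matrix(prob, ncol = nc)
    seg <- list(prob = prob,
                idx = array(as.integer(max.col(pm, ties.method = "first") -
                                         1L), d))
  }
  msk <- SegmentationMask(seg$idx, spacing)
  if (!is.null(model$lookup))
    msk <- denormalizeLabels(msk, model$lookup)
  list(prob = seg$prob, mask = msk)
}

#' Resample and pad a volume/mask pair to a target grid
#'
#' Linear resampling for intensities, nearest neighbour for labels;
#' symmetric zero padding up to `pad_to`. Requesting a padded shape
#' smaller than the data is an error (no silent cropping).
#'
#' @param volume a [DixonVolume-class].
#' @param mask optional [SegmentationMask-class] on the same lattice.
#' @param target_spacing desired voxel spacing in mm (default the
#'   acquisition's 0.7 x 0.7 x 3.0).
#' @param pad_to optional integer length-3 output shape.
#' @return list with `volume` and (if given) `mask` on the new lattice.
#' @export
preprocessVolume <- function(volume, mask = NULL,
                             target_spacing = c(0.7, 0.7, 3.0),
                             pad_to = NULL) {
  sp <- voxelSpacing(volume)
  d <- dim(volume)
  nd <- pmax(1L, as.integer(round(d * sp / target_spacing)))
  if (all(nd == d) && all(abs(sp - target_spacing) < 1e-9)) {
    out_f <- fatSignal(volume); out_w <- waterSignal(volume)
    out_m <- mask
  } else {
    co <- .gridCoords(nd)
    ## centre-aligned mapping between the two lattices
    cx <- (co$cx - (nd[1] + 1) / 2) * target_spacing[1] / sp[1] +
      (d[1] + 1) / 2
    cy <- (co$cy - (nd[2] + 1) / 2) * target_spacing[2] / sp[2] +
      (d[2] + 1) / 2
    cz <- (co$cz - (nd[3] + 1) / 2) * target_spacing[3] / sp[3] +
      (d[3] + 1) / 2
    dm <- as.integer(d)
    out_f <- array(.sampleTrilinear(as.numeric(fatSignal(volume)), dm,
                                    cx, cy, cz, 0), nd)
    out_w <- array(.sampleTrilinear(as.numeric(waterSignal(volume)), dm,
                                    cx, cy, cz, 0), nd)
    out_m <- if (!is.null(mask))
      SegmentationMask(array(as.integer(
        .sampleNearest(as.numeric(mask@labels), dm, cx, cy, cz, 0)), nd),
        target_spacing)
  }
  if (!is.null(pad_to)) {
    pad_to <- as.integer(pad_to)
    if (any(pad_to < nd))
      stop(sprintf("pad_to (%s) smaller than data (%s): refusing to crop",
                   paste(pad_to, collapse = "x"),
                   paste(nd, collapse = "x")), call. = FALSE)
    lo <- (pad_to - nd) %/% 2L
    place <- function(a, fill = 0) {
      out <- array(fill, pad_to)
      out[lo[1] + seq_len(nd[1]), lo[2] + seq_len(nd[2]),
          lo[3] + seq_len(nd[3])] <- a
      out
    }
    out_f <- place(out_f); out_w <- place(out_w)
    if (!is.null(out_m))
      out_m <- SegmentationMask(
        array(as.integer(place(out_m@labels)), pad_to), target_spacing)
  }
  res <- list(volume = DixonVolume(out_f, out_w, target_spacing))
  if (!is.null(mask)) res$mask <- out_m
  res
}
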