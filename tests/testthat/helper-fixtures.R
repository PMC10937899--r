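# Shared fixtures: tiny detector configurations and random prediction sets.

tiny_model_config <- function(num_queries = 8, backbone_stages = 1,
                              base_width = 4, ...) {
  model_config(backbone_depth = 18, hidden_dim = 16,
               num_queries = num_queries, encoder_layers = 1,
               decoder_layers = 1, attention_heads = 2, ffn_dim = 32,
               dropout = 0, backbone_stages = backbone_stages,
               base_width = base_width, ...)
}

random_predictions <- function(n, seed = 1) {
  withr::with_seed(seed, {
    p1 <- runif(n)
    list(boxes = cbind(runif(n, 0.2, 0.8), runif(n, 0.2, 0.8),
                       runif(n, 0.05, 0.3), runif(n, 0.05, 0.3)),
         class_probs = cbind(p1, 1 - p1))
  })
}

random_gt_boxes <- function(m, seed = 1) {
  withr::with_seed(seed + 1000, {
    cbind(runif(m, 0.2, 0.8), runif(m, 0.2, 0.8),
          runif(m, 0.05, 0.3), runif(m, 0.05, 0.3))
  })
}

# exhaustive minimum over all injections of gt rows into prediction slots
brute_force_match_cost <- function(gt_boxes, preds, lambda_iou = 2,
                                   lambda_l1 = 5) {
  M <- nrow(gt_boxes)
  N <- nrow(preds$boxes)
  cost_of <- function(assign) {
    sum(vapply(seq_len(M), function(i) {
      match_cost(list(box = gt_boxes[i, ]),
                 list(class_probs = preds$class_probs[assign[i], ],
                      box = preds$boxes[assign[i], ]),
                 lambda_iou, lambda_l1)
    }, 1))
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    unlist(lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(p) c(v[i], p))
    }), recursive = FALSE)
  }
  slots <- utils::combn(N, M, simplify = FALSE)
  min(vapply(slots, function(s) {
    min(vapply(perms(s), cost_of, 1))
  }, 1))
}
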