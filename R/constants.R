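## item -> maximum score of the combined neurological/behavioural rubric:
## NAS items (neck twist, reflex/extension/postural tests) subtotal 9,
## wellness items (grimace, ears, exploration, eating, drinking, grooming)
## subtotal 10; alive maximum 19, death coded 20.
NBA_ITEM_MAX <- c(
  neck_twist = 1L, righting_reflex = 2L, forepaws_extension = 2L,
  hind_limbs_extension = 2L, postural_reflex = 2L,
  facial_grimace = 2L, ears = 2L, exploration = 2L,
  eating = 1L, drinking = 1L, grooming = 2L
)
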