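pathway	stage	beta	ci_low	ci_high
TAG48:3_IgD-CD38dim_pctBcell	exposure_to_mediator	-0.1312	-0.2431	-0.0193
TAG48:3_IgD-CD38dim_pctBcell	mediator_to_outcome	0.051	0.025	0.077
TAG48:3_IgD-CD38dim_pctBcell	exposure_to_outcome_or	0.9053	0.8364	0.9800
TAG48:3_HLADR++mono_pctLeuko	exposure_to_mediator	-0.1512	-0.2653	-0.0371
TAG48:3_HLADR++mono_pctLeuko	mediator_to_outcome	0.152	0.081	0.224
TAG48:3_HLADR++mono_pctLeuko	exposure_to_outcome_or	0.9053	0.8364	0.9800
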