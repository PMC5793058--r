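seq_id	class	architecture	completeness	stereospecificity	predicted_active	substitutions	length
aos_lox_fusion_001	AOS_LOX_fusion	AOS_LOX_fusion	full_length	indeterminate	TRUE		1066
aos_lox_fusion_002	AOS_LOX_fusion	AOS_LOX_fusion	full_length	indeterminate	TRUE		1066
aos_lox_fusion_003	AOS_LOX_fusion	AOS_LOX_fusion	full_length	S	TRUE		1066
aos_lox_fusion_004	AOS_LOX_fusion	AOS_LOX_fusion	full_length	R	TRUE		1066
aos_lox_fusion_005	AOS_LOX_fusion	AOS_LOX_fusion	full_length	R	TRUE		1066
aos_lox_fusion_006	AOS_LOX_fusion	AOS_LOX_fusion	full_length	indeterminate	TRUE		1066
lox_full_001	LOX_full	LOX	full_length	S	TRUE		693
lox_full_002	LOX_full	LOX	full_length	S	TRUE		693
lox_full_003	LOX_full	LOX	full_length	R	TRUE		693
lox_full_004	LOX_full	LOX	full_length	R	TRUE		693
lox_partial_001	LOX_partial	LOX	partial	S	TRUE		333
lox_partial_002	LOX_partial	LOX	partial	R	TRUE		330
lox_partial_003	LOX_partial	LOX	partial	indeterminate	TRUE		336
lox_partial_004	LOX_partial	LOX	partial	R	TRUE		334
cox_like_001	COX_like	COX_like	NA	indeterminate	NA		600
cox_like_002	COX_like	COX_like	NA	indeterminate	NA		600
cox_like_003	COX_like	COX_like	NA	indeterminate	NA		600
decoy_001	decoy	non_dioxygenase	NA	indeterminate	NA		793
decoy_002	decoy	non_dioxygenase	NA	indeterminate	NA		586
decoy_003	decoy	non_dioxygenase	NA	indeterminate	NA		584
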