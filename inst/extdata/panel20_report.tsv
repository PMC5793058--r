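id	architecture	completeness	stereospecificity	predicted_active	failed_rules	notes	caveat
aos_lox_fusion_001	AOS_LOX_fusion	full_length	indeterminate	TRUE	coffa@780:substitution	AOS-LOX and HPL-LOX fusions are not distinguishable by sequence rules; coffa@780 observed I (stereochemistry unknown)	sequence-based prediction only: stereospecificity is Coffa-predicted and positional specificity is not claimed; catalytic activity requires biochemical confirmation
aos_lox_fusion_002	AOS_LOX_fusion	full_length	indeterminate	TRUE	coffa@780:substitution	AOS-LOX and HPL-LOX fusions are not distinguishable by sequence rules; coffa@780 observed I (stereochemistry unknown)	sequence-based prediction only: stereospecificity is Coffa-predicted and positional specificity is not claimed; catalytic activity requires biochemical confirmation
aos_lox_fusion_003	AOS_LOX_fusion	full_length	S	TRUE		AOS-LOX and HPL-LOX fusions are not distinguishable by sequence rules	sequence-based prediction only: stereospecificity is Coffa-predicted and positional specificity is not claimed; catalytic activity requires biochemical confirmation
aos_lox_fusion_004	AOS_LOX_fusion	full_length	R	TRUE		AOS-LOX and HPL-LOX fusions are not distinguishable by sequence rules	sequence-based prediction only: stereospecificity is Coffa-predicted and positional specificity is not claimed; catalytic activity requires biochemical confirmation
aos_lox_fusion_005	AOS_LOX_fusion	full_length	R	TRUE		AOS-LOX and HPL-LOX fusions are not distinguishable by sequence rules	sequence-based prediction only: stereospecificity is Coffa-predicted and positional specificity is not claimed; catalytic activity requires biochemical confirmation
aos_lox_fusion_006	AOS_LOX_fusion	full_length	indeterminate	TRUE	coffa@780:substitution	AOS-LOX and HPL-LOX fusions are not distinguishable by sequence rules; coffa@780 observed I (stereochemistry unknown)	sequence-based prediction only: stereospecificity is Coffa-predicted and positional specificity is not claimed; catalytic activity requires biochemical confirmation
lox_full_001	LOX	full_length	S	TRUE			sequence-based prediction only: stereospecificity is Coffa-predicted and positional specificity is not claimed; catalytic activity requires biochemical confirmation
lox_full_002	LOX	full_length	S	TRUE			sequence-based prediction only: stereospecificity is Coffa-predicted and positional specificity is not claimed; catalytic activity requires biochemical confirmation
lox_full_003	LOX	full_length	R	TRUE			sequence-based prediction only: stereospecificity is Coffa-predicted and positional specificity is not claimed; catalytic activity requires biochemical confirmation
lox_full_004	LOX	full_length	R	TRUE			sequence-based prediction only: stereospecificity is Coffa-predicted and positional specificity is not claimed; catalytic activity requires biochemical confirmation
lox_partial_001	LOX	partial	S	TRUE			sequence-based prediction only: stereospecificity is Coffa-predicted and positional specificity is not claimed; catalytic activity requires biochemical confirmation
lox_partial_002	LOX	partial	R	TRUE			sequence-based prediction only: stereospecificity is Coffa-predicted and positional specificity is not claimed; catalytic activity requires biochemical confirmation
lox_partial_003	LOX	partial	indeterminate	TRUE	coffa@780:substitution	coffa@780 observed I (stereochemistry unknown)	sequence-based prediction only: stereospecificity is Coffa-predicted and positional specificity is not claimed; catalytic activity requires biochemical confirmation
lox_partial_004	LOX	partial	R	TRUE			sequence-based prediction only: stereospecificity is Coffa-predicted and positional specificity is not claimed; catalytic activity requires biochemical confirmation
cox_like_001	COX_like	NA	indeterminate	NA		COX screen: 81.0% identity over 600 pairs	sequence-based prediction only: stereospecificity is Coffa-predicted and positional specificity is not claimed; catalytic activity requires biochemical confirmation
cox_like_002	COX_like	NA	indeterminate	NA		COX screen: 84.7% identity over 600 pairs	sequence-based prediction only: stereospecificity is Coffa-predicted and positional specificity is not claimed; catalytic activity requires biochemical confirmation
cox_like_003	COX_like	NA	indeterminate	NA		COX screen: 80.8% identity over 600 pairs	sequence-based prediction only: stereospecificity is Coffa-predicted and positional specificity is not claimed; catalytic activity requires biochemical confirmation
decoy_001	non_dioxygenase	NA	indeterminate	NA		COX screen: 15.3% identity over 500 pairs	sequence-based prediction only: stereospecificity is Coffa-predicted and positional specificity is not claimed; catalytic activity requires biochemical confirmation
decoy_002	non_dioxygenase	NA	indeterminate	NA		COX screen: 15.8% identity over 432 pairs	sequence-based prediction only: stereospecificity is Coffa-predicted and positional specificity is not claimed; catalytic activity requires biochemical confirmation
decoy_003	non_dioxygenase	NA	indeterminate	NA		COX screen: 17.0% identity over 466 pairs	sequence-based prediction only: stereospecificity is Coffa-predicted and positional specificity is not claimed; catalytic activity requires biochemical confirmation
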