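dataset	model	precision	recall	f1
yidu_s4k	BiLSTM-CRF	69.43	72.58	70.97
yidu_s4k	ACNN	83.07	87.29	85.13
yidu_s4k	ELMo-lattice-LSTM-CRF	84.69	85.35	85.02
yidu_s4k	ELMo-BiLSTM-CRF	NA	NA	85.16
yidu_s4k	ELMo-ET-CRF	82.08	86.12	85.59
yidu_s4k	MSD_DT_NER	86.09	87.29	86.69
yidu_s4k	BERT-BiLSTM-CRF	89.07	83.67	86.29
yidu_s4k	RoBERTa-wwm-BiLSTM-CRF	90.08	86.90	88.46
yidu_s4k	multisemantic-fusion	90.37	88.22	89.28
self_annotated	BiLSTM-CRF	81.98	77.10	79.47
self_annotated	BERT-BiLSTM-CRF	82.48	80.86	81.66
self_annotated	RoBERTa-wwm-BiLSTM-CRF	84.23	82.86	83.54
self_annotated	multisemantic-fusion	84.24	84.99	84.61
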