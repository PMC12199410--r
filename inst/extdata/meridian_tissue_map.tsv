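meridian	tissues
lung	lung
liver	liver
bladder	urinary bladder
heart	heart muscle
spleen	spleen
kidney	kidney
stomach	stomach
large intestine	colon;rectum
small intestine	small intestine
gallbladder	gallbladder
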