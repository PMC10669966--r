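sarcoma_type,intensity_0,intensity_1,intensity_2,intensity_3
Fibrosarcoma,7,2,1,0
Gastrointestinal stromal tumor,0,0,8,19
Liposarcoma,46,24,14,3
Leiomyosarcoma,19,17,17,6
Malignant fibrohistiocytoma,133,67,19,3
Malignant peripheral nerve sheath tumor,11,4,3,2
Myxofibrosarcoma,27,14,7,0
Sarcoma (not otherwise specified),14,12,5,2
Synovial sarcoma,29,4,3,1
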