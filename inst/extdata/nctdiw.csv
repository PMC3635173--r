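scanner_class,ctdi_spec,kvp,nctdiw_mgy_per_100mas
single_slice,head,80,7.0
single_slice,head,100,13.0
single_slice,head,120,20.0
single_slice,head,140,28.0
single_slice,body,80,3.5
single_slice,body,100,6.5
single_slice,body,120,10.0
single_slice,body,140,14.0
multi_slice,head,80,6.0
multi_slice,head,100,11.0
multi_slice,head,120,17.0
multi_slice,head,140,24.0
multi_slice,body,80,3.0
multi_slice,body,100,5.5
multi_slice,body,120,8.5
multi_slice,body,140,12.0
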