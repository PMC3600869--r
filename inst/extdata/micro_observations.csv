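"station_id","lon","lat","date","pollutant","value"
"s1",0,0,1,"A",0.919353176380558
"s2",30,5,1,"A",2.38802412815311
"s3",10,40,1,"A",0.222356245730507
"s1",0,0,1,"B",-0.406909693462113
"s2",30,5,1,"B",-1.44314479292944
"s3",10,40,1,"B",0.636519201981131
"s1",0,0,2,"A",0.349136064580674
"s2",30,5,2,"A",1.10887716226468
"s3",10,40,2,"A",1.99266506574726
"s1",0,0,2,"B",-0.429795796102982
"s2",30,5,2,"B",-1.35889366429689
"s3",10,40,2,"B",-1.10427473573177
"s1",0,0,3,"A",0.0223962393853195
"s3",10,40,3,"A",-0.849415927580904
"s1",0,0,3,"B",-0.126541032292166
"s2",30,5,3,"B",-0.146303764462634
"s3",10,40,3,"B",-0.412071176732973
"s1",0,0,4,"A",3.22301258930083
"s2",30,5,4,"A",2.5368428905365
"s3",10,40,4,"A",0.762697237463654
"s1",0,0,4,"B",0.453504005775219
"s2",30,5,4,"B",1.8159422717699
"s3",10,40,4,"B",0.122491381738768
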