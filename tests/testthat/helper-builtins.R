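# Frozen fixture of the five built-in definitions: every limit and trigger
# time, verbatim. Any drift in the built-in scenario library fails here.
frozenBuiltins <- function() {
  read.csv(text = '
scenario,channel,fallback,kind,direction,threshold,unit,duration,window,scope
SVT+BP,HR,Pulse,relative_change,rise,40,percent,NA,59,NA
SVT+BP,ARTsys,NA,relative_change,fall,15,percent,NA,59,NA
SVT+BP,Pulse,HR,absolute_sustained,above,110,native,20,NA,NA
Vtach+BP,HR,Pulse,relative_change,rise,30,native,NA,20,NA
Vtach+BP,VtachFlag,NA,flag_present,above,1,native,5,NA,NA
Vtach+BP,ARTsys,NA,relative_change,fall,30,percent,NA,20,NA
Vtach+BP,Pulse,HR,absolute_sustained,above,110,native,10,NA,NA
LV shock,ARTsys,NA,absolute_sustained,below,78,native,300,NA,NA
LV shock,CVPmean,NA,absolute_sustained,below,16,native,300,NA,NA
LV shock,PAPdia,NA,absolute_sustained,above,16,native,300,NA,NA
LV shock,Perf,NA,absolute_sustained,below,1.2,native,300,NA,NA
Tamponade,ARTsys,NA,absolute_sustained,below,78,native,180,NA,NA
Tamponade,CVPmean,NA,absolute_sustained,above,16,native,180,NA,NA
Tamponade,Perf,NA,relative_change,fall,20,percent,NA,180,NA
Tamponade,PAPdia,NA,absolute_sustained,above,16,native,180,NA,NA
Hypovolemia,ARTmean,NA,absolute_sustained,below,50,native,300,NA,NA
Hypovolemia,CVPmean,NA,absolute_sustained,below,5,native,300,NA,NA
Hypovolemia,Perf,NA,relative_change,fall,20,percent,NA,120,600
Hypovolemia,NIBPm,NA,absolute_sustained,below,55,native,300,NA,NA
', stringsAsFactors = FALSE)
}

flattenRules <- function(rules) {
  do.call(rbind, lapply(rules, function(r)
    do.call(rbind, lapply(r@triggers, function(tr)
      data.frame(scenario = r@name, channel = tr@channel,
                 fallback = tr@fallback, kind = tr@kind,
                 direction = tr@direction, threshold = tr@threshold,
                 unit = tr@unit, duration = tr@duration,
                 window = tr@window, scope = tr@scope,
                 stringsAsFactors = FALSE)))))
}

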